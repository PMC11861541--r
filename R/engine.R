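# Exposure engine: phase-wise potential dermal exposure, PPE attenuation,
# absorbed dose and the risk index as a percentage of AOEL x body weight.
#
# The calculation chain follows the structure common to the German,
# UK-POEM and EFSA operator-exposure models: an external dose equal to the
# handled or applied mass times a contact/deposition fraction, attenuated
# region-by-region by (1 - protection factor), then multiplied by the dermal
# absorption coefficient of the active ingredient. Mixing-and-loading and
# maintenance are hands-only phases (the concentrate and the dilute mix are
# handled manually); the application deposit is split over five body
# regions by configurable surface weights.

MG_PER_G <- 1000
L_PER_HL <- 100
MIX_DENSITY_KG_PER_L <- 1  # dilute aqueous spray mix

phase_exposure <- function(phase, potential, skin_loading, dermal_absorption,
                           excluded = FALSE, detail = list()) {
  structure(list(phase = phase,
                 potential_exposure_mg = potential,
                 retained_by_ppe_mg = potential - skin_loading,
                 skin_loading_mg = skin_loading,
                 absorbed_mg = skin_loading * dermal_absorption,
                 excluded = excluded,
                 detail = detail),
            class = "phase_exposure")
}

zero_phase <- function(phase, excluded, reason) {
  phase_exposure(phase, 0, 0, 0, excluded = excluded,
                 detail = list(reason = reason))
}

#' Mass of active ingredient applied over the treated area
#'
#' `GAP rate (g formulation/ha) x area (ha) x AI concentration (g/100 g)`,
#' converted to mg of active ingredient.
#'
#' @param product A `product` from [get_product()].
#' @param area_ha Treated area in hectares (> 0).
#' @return Applied active-ingredient mass in mg.
#' @export
ai_mass_applied <- function(product, area_ha) {
  stopifnot(area_ha > 0)
  product$gap_g_per_ha * area_ha * MG_PER_G * product$concentration_pct / 100
}

#' Number of tank loads prepared in the working day
#'
#' @param spray_volume_hl_per_ha Applied solution volume, hL/ha.
#' @param area_ha Treated area, ha.
#' @param tank_volume_l Tank capacity, L.
#' @return `ceiling(spray volume in L / tank volume)`, at least 1.
#' @export
n_tank_loads <- function(spray_volume_hl_per_ha, area_ha, tank_volume_l) {
  stopifnot(spray_volume_hl_per_ha > 0, area_ha > 0, tank_volume_l > 0)
  max(1L, as.integer(ceiling(spray_volume_hl_per_ha * L_PER_HL * area_ha /
                               tank_volume_l)))
}

#' Mixing-and-loading phase exposure
#'
#' The operator handles the concentrated formulation; a small contact
#' fraction of the handled mass (banded on the AI concentration, see
#' [formulation_exposure_fraction()]) reaches the hands. Potential exposure
#' is expressed in mg of active ingredient; only the hands-phase gloves
#' attenuate it. The ledger is all-zero when the phase is skipped
#' (loading-station scenario) or the product comes in pre-dosed soluble
#' bags.
#'
#' @param scenario A `scenario` object.
#' @param tables A `reference_tables` object.
#' @param settings An [engine_settings()] object.
#' @return A `phase_exposure` ledger: potential exposure, PPE-retained mass,
#'   skin loading, absorbed dose (all mg AI).
#' @export
exposure_mixing_loading <- function(scenario, tables,
                                    settings = engine_settings()) {
  product <- get_product(tables, scenario$product_name)
  if (scenario$skip_mixing_loading)
    return(zero_phase("mixing_loading", TRUE, "phase skipped (loading station)"))
  if (product$formulation == "soluble_bag")
    return(zero_phase("mixing_loading", FALSE,
                      "pre-dosed soluble bags: no contact with the product"))
  fraction <- formulation_exposure_fraction(tables, product$formulation,
                                            product$concentration_pct)
  handled_mg <- product$gap_g_per_ha * scenario$area_ha * MG_PER_G
  potential <- handled_mg * fraction * product$concentration_pct / 100
  pf <- protection_factor(tables, scenario$ppe$mixing_loading$hands)
  skin <- potential * (1 - pf)
  phase_exposure("mixing_loading", potential, skin, product$dermal_absorption,
                 detail = list(contact_fraction = fraction,
                               handled_formulation_mg = handled_mg,
                               hands_item = scenario$ppe$mixing_loading$hands,
                               hands_pf = pf))
}

#' Application phase exposure
#'
#' The deposition factor (ppm) gives the fraction of applied mix deposited
#' on the operator; because it is a mass ratio, it applies equally to the
#' active ingredient carried by the mix, so potential AI exposure is
#' `applied AI mass x ppm x 1e-6`. The deposit is split over the five body
#' regions by `settings$body_region_weights` and each region is attenuated
#' by the complement of its PPE item's protection factor.
#'
#' @inheritParams exposure_mixing_loading
#' @return A `phase_exposure` ledger.
#' @export
exposure_application <- function(scenario, tables,
                                 settings = engine_settings()) {
  product <- get_product(tables, scenario$product_name)
  ppm <- deposition_factor(tables, scenario$application$equipment,
                           scenario$crop$height,
                           scenario$application$pressure_bar, settings)
  potential <- ai_mass_applied(product, scenario$area_ha) * ppm * 1e-6
  weights <- settings$body_region_weights
  regions <- lapply(BODY_REGIONS, function(region) {
    item <- scenario$ppe$application[[region]]
    pf <- protection_factor(tables, item)
    list(region = region, weight = unname(weights[[region]]), item = item,
         pf = pf, skin_loading_mg = potential * weights[[region]] * (1 - pf))
  })
  skin <- sum(vapply(regions, `[[`, numeric(1), "skin_loading_mg"))
  phase_exposure("application", potential, skin, product$dermal_absorption,
                 detail = list(deposition_ppm = ppm, regions = regions))
}

#' Maintenance-and-cleaning phase exposure
#'
#' The operator handles the dilute spray solution rather than the
#' concentrate. The handled mass defaults to one tank load at density
#' 1 kg/L; a contact fraction of it reaches the hands, carrying the mix's
#' AI concentration (applied AI mass / total mix mass). Hands-only PPE
#' attenuation, as in mixing and loading.
#'
#' @inheritParams exposure_mixing_loading
#' @return A `phase_exposure` ledger.
#' @export
exposure_maintenance <- function(scenario, tables,
                                 settings = engine_settings()) {
  product <- get_product(tables, scenario$product_name)
  app <- scenario$application
  handled_kg <- settings$maintenance_handled_mass_kg
  if (is.null(handled_kg))
    handled_kg <- app$tank_volume_l * MIX_DENSITY_KG_PER_L
  mix_kg <- app$spray_volume_hl_per_ha * L_PER_HL * scenario$area_ha *
    MIX_DENSITY_KG_PER_L
  mix_conc_mg_per_kg <- ai_mass_applied(product, scenario$area_ha) / mix_kg
  potential <- handled_kg * settings$maintenance_contact_fraction *
    mix_conc_mg_per_kg
  pf <- protection_factor(tables, scenario$ppe$maintenance$hands)
  skin <- potential * (1 - pf)
  phase_exposure("maintenance", potential, skin, product$dermal_absorption,
                 detail = list(handled_mass_kg = handled_kg,
                               contact_fraction = settings$maintenance_contact_fraction,
                               mix_concentration_mg_per_kg = mix_conc_mg_per_kg,
                               hands_item = scenario$ppe$maintenance$hands,
                               hands_pf = pf))
}

#' Classify a risk index into the three-tier verdict
#'
#' Green ("safe") strictly below the green threshold; red ("unsafe",
#' application unadvisable) strictly above the red threshold; yellow
#' ("borderline") in between, boundaries included.
#'
#' @param risk_percent Absorbed daily dose as percent of AOEL x body weight.
#' @param settings An [engine_settings()] object supplying the thresholds.
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
classify_tier <- function(risk_percent, settings = engine_settings()) {
  stopifnot(risk_percent >= 0)
  if (risk_percent < settings$tier_green_lt) "green"
  else if (risk_percent > settings$tier_red_gt) "red"
  else "yellow"
}

#' Assess a full treatment scenario
#'
#' Runs the three phase estimators, sums the absorbed doses over the
#' workday, computes the acceptable dose `AOEL x body weight`, the risk
#' index `100 x absorbed / acceptable`, and the traffic-light tier. The
#' returned audit map records every table value, multiplier and default
#' used, so that a trained reader can reproduce the numbers by hand.
#'
#' @param scenario A `scenario` object (see [parse_scenario()]).
#' @param tables A `reference_tables` object.
#' @param settings An [engine_settings()] object.
#' @return An object of class `risk_result` with elements `phases` (list of
#'   `phase_exposure`), `total_absorbed_mg`, `acceptable_dose_mg`,
#'   `risk_percent`, `tier`, `n_tank_loads`, `warnings` and `audit`.
#' @export
assess_scenario <- function(scenario, tables, settings = engine_settings()) {
  stopifnot(inherits(scenario, "scenario"), inherits(tables, "reference_tables"))
  findings <- validate_scenario(scenario, tables)
  errors <- findings[findings$severity == "error", ]
  if (nrow(errors))
    stop(paste0("invalid scenario: ",
                paste(sprintf("[%s] %s", errors$field, errors$message),
                      collapse = "; ")), call. = FALSE)
  product <- get_product(tables, scenario$product_name)

  phases <- list(
    mixing_loading = exposure_mixing_loading(scenario, tables, settings),
    application    = exposure_application(scenario, tables, settings),
    maintenance    = exposure_maintenance(scenario, tables, settings))
  total <- sum(vapply(phases, `[[`, numeric(1), "absorbed_mg"))
  acceptable <- product$aoel_mg_per_kg * scenario$body_weight_kg
  risk <- 100 * total / acceptable

  ppe_audit <- lapply(scenario$ppe, function(sel)
    lapply(sel, function(item)
      list(item = item, pf = protection_factor(tables, item),
           source = ppe_source(tables, item))))

  structure(list(
    phases = phases,
    total_absorbed_mg = total,
    acceptable_dose_mg = acceptable,
    risk_percent = risk,
    tier = classify_tier(risk, settings),
    n_tank_loads = n_tank_loads(scenario$application$spray_volume_hl_per_ha,
                                scenario$area_ha,
                                scenario$application$tank_volume_l),
    warnings = findings[findings$severity != "error", , drop = FALSE],
    audit = list(
      product = product[c("name", "ai_name", "formulation",
                          "concentration_pct", "gap_g_per_ha",
                          "aoel_mg_per_kg", "dermal_absorption")],
      area_ha = scenario$area_ha,
      body_weight_kg = scenario$body_weight_kg,
      ai_mass_applied_mg = ai_mass_applied(product, scenario$area_ha),
      crop_height = scenario$crop$height,
      crop_height_multiplier = crop_height_multiplier(settings,
                                                      scenario$crop$height),
      pressure_bar = scenario$application$pressure_bar,
      pressure_multiplier = pressure_multiplier(
        settings, scenario$application$pressure_bar),
      equipment = scenario$application$equipment,
      ppe = ppe_audit,
      body_region_weights = as.list(settings$body_region_weights),
      maintenance_contact_fraction = settings$maintenance_contact_fraction,
      tier_thresholds = list(green_lt = settings$tier_green_lt,
                             red_gt = settings$tier_red_gt),
      defaults_applied = attr(scenario, "parse_log"))),
    class = "risk_result")
}

tier_token <- function(tier) {
  switch(tier, green = "✅", yellow = "⚠️", red = "⛔")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("%s risk index: %s%% of AOEL (tier %s)\n", tier_token(x$tier),
              format(signif(x$risk_percent, 3)), x$tier))
  cat(sprintf("  absorbed %s mg vs acceptable %s mg/day; %d tank load(s)\n",
              format(signif(x$total_absorbed_mg, 3)),
              format(signif(x$acceptable_dose_mg, 3)), x$n_tank_loads))
  for (p in x$phases)
    cat(sprintf("  %-15s %s\n", p$phase,
                if (p$excluded) "excluded"
                else sprintf("absorbed %s mg (potential %s mg)",
                             format(signif(p$absorbed_mg, 3)),
                             format(signif(p$potential_exposure_mg, 3)))))
  invisible(x)
}
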