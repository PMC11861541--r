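# Independent closed-form oracle for the full risk index. Coded as direct
# arithmetic over the raw table data frames, deliberately sharing no code
# path with the engine's phase estimators.

oracle_assess <- function(sc, tb, st = engine_settings()) {
  prod <- tb$products[match(toupper(sc$product_name),
                            toupper(tb$products$product_name)), ]
  conc <- prod$concentration_pct
  derm <- prod$dermal_absorption_pct / 100
  pf <- function(item) if (item == "none") 0 else
    tb$protection$fraction[match(item, tb$protection$item)]

  # mixing & loading (hands only, banded contact fraction on concentrate)
  ml <- if (sc$skip_mixing_loading || prod$formulation == "soluble_bag") 0 else {
    frow <- if (prod$formulation == "soluble_granule") "liquid_concentrate"
            else prod$formulation
    bands <- tb$formulation[tb$formulation$formulation == frow, ]
    frac <- bands$fraction[bands$band_lo <= conc &
                             (conc < bands$band_hi | bands$band_hi == 100)][1]
    prod$gap_g_per_ha * sc$area_ha * 1000 * frac * conc / 100 *
      (1 - pf(sc$ppe$mixing_loading$hands)) * derm
  }

  # application (deposition ppm split over body regions)
  ai_mg <- prod$gap_g_per_ha * sc$area_ha * 1000 * conc / 100
  pm <- st$pressure_multipliers
  p <- sc$application$pressure_bar
  p_mult <- {
    hit <- which(pm$lo <= p & (p < pm$hi | pm$hi == Inf))
    if (length(hit)) pm$multiplier[hit[1]] else 1
  }
  ppm <- tb$deposition$ppm[match(sc$application$equipment,
                                 tb$deposition$equipment)] *
    st$crop_height_multipliers[[sc$crop$height]] * p_mult
  w <- st$body_region_weights
  pass <- sum(vapply(names(w), function(r)
    w[[r]] * (1 - pf(sc$ppe$application[[r]])), numeric(1)))
  app <- ai_mg * ppm * 1e-6 * pass * derm

  # maintenance (dilute mix on the hands)
  handled_kg <- if (is.null(st$maintenance_handled_mass_kg))
    sc$application$tank_volume_l else st$maintenance_handled_mass_kg
  mix_kg <- sc$application$spray_volume_hl_per_ha * 100 * sc$area_ha
  man <- handled_kg * st$maintenance_contact_fraction * (ai_mg / mix_kg) *
    (1 - pf(sc$ppe$maintenance$hands)) * derm

  total <- ml + app + man
  risk <- 100 * total / (prod$aoel_mg_per_kg * sc$body_weight_kg)
  list(ml = ml, app = app, man = man, total = total, risk = risk)
}
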