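# Report rendering and the what-if improvement search.

#' Render a risk result as JSON or Markdown
#'
#' JSON carries the complete machine-readable result: phase ledger, totals,
#' tier, tank loads, warnings and the full parameter-audit map, at full
#' numeric precision. Markdown is the printable surrogate: tier pictogram,
#' per-phase table (a skipped phase is shown as "excluded", not as a
#' computed zero), warnings, and the parameter-audit appendix; displayed
#' numbers are rounded to 3 significant figures while the tier is always
#' decided on the unrounded value.
#'
#' @param result A `risk_result` from [assess_scenario()].
#' @param scenario The assessed `scenario`.
#' @param format `"json"` or `"markdown"`.
#' @return A single string.
#' @export
render_report <- function(result, scenario, format = c("json", "markdown")) {
  stopifnot(inherits(result, "risk_result"), inherits(scenario, "scenario"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      scenario = unclass(scenario),
      phases = lapply(result$phases, unclass),
      total_absorbed_mg = result$total_absorbed_mg,
      acceptable_dose_mg = result$acceptable_dose_mg,
      risk_percent = result$risk_percent,
      tier = result$tier,
      n_tank_loads = result$n_tank_loads,
      warnings = result$warnings,
      audit = result$audit)
    # 17 significant digits: doubles survive the decimal round-trip exactly
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = I(17), null = "null")))
  }

  s3 <- function(x) format(signif(x, 3))
  lines <- c(
    sprintf("# Pesticide risk assessment — %s", scenario$product_name),
    "",
    sprintf("%s **Tier: %s** — risk index **%s%% of AOEL**",
            tier_token(result$tier), result$tier, s3(result$risk_percent)),
    "",
    sprintf("Crop: %s (%s) | Area: %g ha | Equipment: %s | Tank loads: %d",
            scenario$crop$name, scenario$crop$height, scenario$area_ha,
            scenario$application$equipment, result$n_tank_loads),
    "",
    "| Phase | Potential exposure (mg AI) | Retained by PPE (mg) | Skin loading (mg) | Absorbed (mg) |",
    "|---|---|---|---|---|")
  for (p in result$phases) {
    lines <- c(lines, if (p$excluded)
      sprintf("| %s | excluded | excluded | excluded | excluded |", p$phase)
      else sprintf("| %s | %s | %s | %s | %s |", p$phase,
                   s3(p$potential_exposure_mg), s3(p$retained_by_ppe_mg),
                   s3(p$skin_loading_mg), s3(p$absorbed_mg)))
  }
  lines <- c(lines, "",
             sprintf("Total absorbed: **%s mg/day** vs acceptable dose (AOEL × body weight): **%s mg/day**",
                     s3(result$total_absorbed_mg), s3(result$acceptable_dose_mg)))
  if (nrow(result$warnings)) {
    lines <- c(lines, "", "## Warnings", "")
    lines <- c(lines, sprintf("- (%s) `%s`: %s", result$warnings$severity,
                              result$warnings$field, result$warnings$message))
  }
  a <- result$audit
  lines <- c(lines, "", "## Parameter audit", "",
             sprintf("- product: %s (AI %s, %s, %g g/100 g, GAP %g g/ha)",
                     a$product$name, a$product$ai_name, a$product$formulation,
                     a$product$concentration_pct, a$product$gap_g_per_ha),
             sprintf("- AOEL %g mg/kg bw/day, dermal absorption %g%%, body weight %g kg",
                     a$product$aoel_mg_per_kg, 100 * a$product$dermal_absorption,
                     a$body_weight_kg),
             sprintf("- AI mass applied: %s mg over %g ha",
                     s3(a$ai_mass_applied_mg), a$area_ha),
             sprintf("- deposition: %s at %g bar, %s crop (multipliers %g × %g)",
                     a$equipment, a$pressure_bar, a$crop_height,
                     a$crop_height_multiplier, a$pressure_multiplier),
             sprintf("- tier thresholds: green < %g%%, red > %g%%",
                     a$tier_thresholds$green_lt, a$tier_thresholds$red_gt))
  for (phase in names(a$ppe)) {
    worn <- a$ppe[[phase]]
    parts <- vapply(names(worn), function(region) {
      w <- worn[[region]]
      sprintf("%s=%s (PF %g%s)", region, w$item, w$pf,
              if (identical(w$source, "default")) ", package default" else "")
    }, character(1))
    lines <- c(lines, sprintf("- PPE %s: %s", phase, paste(parts, collapse = "; ")))
  }
  if (length(a$defaults_applied))
    lines <- c(lines, sprintf("- defaults filled at parse time: %s",
                              paste(a$defaults_applied, collapse = "; ")))
  paste(lines, collapse = "\n")
}

upgrade_moves <- function(scenario, tables) {
  moves <- list()
  for (phase in WORK_PHASES) for (region in BODY_REGIONS) {
    current_pf <- protection_factor(tables, scenario$ppe[[phase]][[region]])
    for (item in items_for_region(tables, region)) {
      pf <- protection_factor(tables, item)
      if (pf > current_pf)
        moves[[length(moves) + 1L]] <- list(
          type = "ppe", phase = phase, region = region, item = item,
          slot = paste("ppe", phase, region, sep = "."),
          label = sprintf("ppe.%s.%s -> %s", phase, region, item))
    }
  }
  current_ppm <- tables$deposition$ppm[
    tables$deposition$equipment == scenario$application$equipment]
  for (i in seq_len(nrow(tables$deposition))) {
    if (tables$deposition$ppm[i] < current_ppm)
      moves[[length(moves) + 1L]] <- list(
        type = "equipment", equipment = tables$deposition$equipment[i],
        slot = "equipment",
        label = sprintf("equipment -> %s", tables$deposition$equipment[i]))
  }
  moves
}

apply_moves <- function(scenario, moves) {
  for (m in moves) {
    if (m$type == "ppe") scenario$ppe[[m$phase]][[m$region]] <- m$item
    else scenario$application$equipment <- m$equipment
  }
  scenario
}

#' Search for minimal scenario improvements
#'
#' Exhaustively explores the finite upgrade lattice — replacing any PPE item
#' in any phase/region by a higher-protection item, or the spraying
#' equipment by one with a lower deposition factor — in change sets of up to
#' `max_changes` moves (one move per slot), re-assessing each candidate.
#' Agronomic givens (product, area, AOEL) are never modified. Only change
#' sets that reach a strictly better tier than the current scenario are
#' returned, sorted by (tier, fewest changes, new risk).
#'
#' @param scenario A `scenario` object whose current tier is not green.
#' @param tables A `reference_tables` object.
#' @param settings An [engine_settings()] object.
#' @param max_changes Maximum number of simultaneous upgrades (small
#'   integer).
#' @return A list of class `improvement_list`; each element has `changes`
#'   (character labels), `moves`, `risk_percent` and `tier`. Empty when no
#'   combination reaches a better tier, or (with attribute `"note"`) when
#'   the scenario is already green (no-op) or `max_changes` is 0.
#' @export
suggest_improvements <- function(scenario, tables,
                                 settings = engine_settings(),
                                 max_changes = 2) {
  baseline <- assess_scenario(scenario, tables, settings)
  empty <- structure(list(), class = "improvement_list",
                     baseline_risk = baseline$risk_percent,
                     baseline_tier = baseline$tier)
  if (baseline$tier == "green") {
    attr(empty, "note") <- "scenario is already green; nothing to improve"
    return(empty)
  }
  if (max_changes < 1) return(empty)

  moves <- upgrade_moves(scenario, tables)
  if (!length(moves)) return(empty)
  tier_rank <- c(green = 1, yellow = 2, red = 3)

  results <- list()
  explore <- function(chosen, start) {
    if (length(chosen)) {
      set <- moves[chosen]
      res <- assess_scenario(apply_moves(scenario, set), tables, settings)
      if (tier_rank[[res$tier]] < tier_rank[[baseline$tier]])
        results[[length(results) + 1L]] <<- list(
          changes = vapply(set, `[[`, character(1), "label"),
          moves = set,
          risk_percent = res$risk_percent,
          tier = res$tier)
    }
    if (length(chosen) >= max_changes) return()
    used_slots <- vapply(moves[chosen], `[[`, character(1), "slot")
    for (i in seq_along(moves)) {
      if (i < start || moves[[i]]$slot %in% used_slots) next
      explore(c(chosen, i), i + 1L)
    }
  }
  explore(integer(0), 1L)

  if (!length(results)) return(empty)
  ord <- order(vapply(results, function(r) tier_rank[[r$tier]], numeric(1)),
               vapply(results, function(r) length(r$changes), integer(1)),
               vapply(results, `[[`, numeric(1), "risk_percent"))
  structure(results[ord], class = "improvement_list",
            baseline_risk = baseline$risk_percent,
            baseline_tier = baseline$tier)
}

#' @export
print.improvement_list <- function(x, ...) {
  note <- attr(x, "note")
  cat(sprintf("Baseline: %s%% of AOEL (tier %s)\n",
              format(signif(attr(x, "baseline_risk"), 3)),
              attr(x, "baseline_tier")))
  if (!is.null(note)) cat(note, "\n")
  if (!length(x)) {
    if (is.null(note)) cat("no change set reaches a better tier\n")
    return(invisible(x))
  }
  for (i in seq_along(x))
    cat(sprintf("%2d. [%s, %s%%] %s\n", i, x[[i]]$tier,
                format(signif(x[[i]]$risk_percent, 3)),
                paste(x[[i]]$changes, collapse = " + ")))
  invisible(x)
}
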