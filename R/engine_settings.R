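# Engine settings house every model constant that the printed reference
# tables do not fix, so recalibration needs no code change.

#' Exposure-engine settings
#'
#' Collects every tunable constant of the calculation chain:
#'
#' * `body_region_weights` — split of the application-phase deposit over the
#'   five PPE regions; must sum to 1. Defaults follow adult body-surface
#'   proportions (head 0.06, face 0.04, hands 0.20, body 0.60, feet 0.10).
#' * `maintenance_contact_fraction` — fraction of the handled dilute mix that
#'   reaches the hands during cleaning/maintenance. Default 3e-4, the
#'   dilute-liquid (below-30-percent band) contact fraction, since spray mix is always
#'   dilute.
#' * `maintenance_handled_mass_kg` — mass of dilute mix handled during
#'   maintenance; `NULL` (default) means one tank volume at density 1 kg/L.
#' * `tier_green_lt`, `tier_red_gt` — traffic-light thresholds in percent of
#'   AOEL: green strictly below `tier_green_lt`, red strictly above
#'   `tier_red_gt`, yellow between. Defaults 50 and 100; 100 percent of AOEL is
#'   the regulatory acceptability bound.
#' * `crop_height_multipliers` — named multipliers on the deposition factor
#'   for `low` and `high` crops (both default 1: no effect is invented where
#'   no value is established).
#' * `pressure_multipliers` — data frame `lo, hi, multiplier` of spray
#'   pressure bands (bar) scaling the deposition factor; default a single
#'   all-pressure band with multiplier 1.
#'
#' @param body_region_weights Named numeric, regions head/face/hands/body/feet.
#' @param maintenance_contact_fraction Dimensionless fraction.
#' @param maintenance_handled_mass_kg Mass in kg, or `NULL`.
#' @param tier_green_lt,tier_red_gt Percent-of-AOEL thresholds.
#' @param crop_height_multipliers Named numeric with entries `low`, `high`.
#' @param pressure_multipliers Data frame with columns `lo`, `hi`,
#'   `multiplier`.
#' @return An object of class `engine_settings`.
#' @export
engine_settings <- function(body_region_weights = c(head = 0.06, face = 0.04,
                                                    hands = 0.20, body = 0.60,
                                                    feet = 0.10),
                            maintenance_contact_fraction = 3e-4,
                            maintenance_handled_mass_kg = NULL,
                            tier_green_lt = 50,
                            tier_red_gt = 100,
                            crop_height_multipliers = c(low = 1, high = 1),
                            pressure_multipliers = data.frame(
                              lo = 0, hi = Inf, multiplier = 1)) {
  w <- body_region_weights[BODY_REGIONS]
  if (anyNA(w))
    stop("body_region_weights must name all of: ",
         paste(BODY_REGIONS, collapse = ", "), call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("body_region_weights must sum to 1 (got %.12g)", sum(w)),
         call. = FALSE)
  if (any(w < 0)) stop("body_region_weights must be non-negative", call. = FALSE)
  if (maintenance_contact_fraction < 0 || maintenance_contact_fraction > 1)
    stop("maintenance_contact_fraction must be in [0,1]", call. = FALSE)
  if (!is.null(maintenance_handled_mass_kg) &&
      (!is.finite(maintenance_handled_mass_kg) || maintenance_handled_mass_kg < 0))
    stop("maintenance_handled_mass_kg must be >= 0 or NULL", call. = FALSE)
  if (tier_green_lt > tier_red_gt)
    stop("tier_green_lt must not exceed tier_red_gt", call. = FALSE)
  ch <- crop_height_multipliers[c("low", "high")]
  if (anyNA(ch) || any(ch < 0))
    stop("crop_height_multipliers must name non-negative 'low' and 'high'",
         call. = FALSE)
  pm <- pressure_multipliers
  if (!all(c("lo", "hi", "multiplier") %in% names(pm)) || any(pm$multiplier < 0))
    stop("pressure_multipliers needs non-negative columns lo, hi, multiplier",
         call. = FALSE)
  structure(list(body_region_weights = w,
                 maintenance_contact_fraction = maintenance_contact_fraction,
                 maintenance_handled_mass_kg = maintenance_handled_mass_kg,
                 tier_green_lt = tier_green_lt,
                 tier_red_gt = tier_red_gt,
                 crop_height_multipliers = ch,
                 pressure_multipliers = pm),
            class = "engine_settings")
}

crop_height_multiplier <- function(settings, crop_height) {
  unname(settings$crop_height_multipliers[[crop_height]])
}

pressure_multiplier <- function(settings, pressure_bar) {
  if (is.null(pressure_bar)) return(1)
  pm <- settings$pressure_multipliers
  hit <- which(pm$lo <= pressure_bar & (pressure_bar < pm$hi | pm$hi == Inf))
  if (!length(hit)) 1 else pm$multiplier[hit[1]]
}

#' Read engine settings from a YAML (or JSON) file
#'
#' Keys mirror the arguments of [engine_settings()]; absent keys keep their
#' defaults. `pressure_multipliers` is given as a list of
#' `{lo, hi, multiplier}` maps.
#'
#' @param path Path to the settings file.
#' @return An `engine_settings` object.
#' @export
read_engine_settings <- function(path) {
  if (!file.exists(path))
    stop_load("settings file not found: '%s'", path)
  raw <- parse_structured_text(paste(readLines(path, warn = FALSE),
                                     collapse = "\n"))
  args <- list()
  if (!is.null(raw$body_region_weights))
    args$body_region_weights <- unlist(raw$body_region_weights)
  for (key in c("maintenance_contact_fraction", "maintenance_handled_mass_kg",
                "tier_green_lt", "tier_red_gt"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$crop_height_multipliers))
    args$crop_height_multipliers <- unlist(raw$crop_height_multipliers)
  if (!is.null(raw$pressure_multipliers)) {
    pm <- do.call(rbind, lapply(raw$pressure_multipliers, function(b)
      data.frame(lo = b$lo, hi = if (is.null(b$hi)) Inf else b$hi,
                 multiplier = b$multiplier)))
    args$pressure_multipliers <- pm
  }
  do.call(engine_settings, args)
}

#' @export
print.engine_settings <- function(x, ...) {
  cat("Exposure-engine settings\n")
  cat("  region weights      :",
      paste(sprintf("%s %.2f", names(x$body_region_weights),
                    x$body_region_weights), collapse = ", "), "\n")
  cat("  maintenance contact :", format(x$maintenance_contact_fraction), "\n")
  cat("  maintenance mass    :",
      if (is.null(x$maintenance_handled_mass_kg)) "one tank load (1 kg/L)"
      else paste(x$maintenance_handled_mass_kg, "kg"), "\n")
  cat(sprintf("  tiers               : green < %g%%, red > %g%% of AOEL\n",
              x$tier_green_lt, x$tier_red_gt))
  invisible(x)
}
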