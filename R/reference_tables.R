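# Reference parameter tables: formulation contact fractions, equipment
# deposition coefficients, PPE protection factors, and the product database.
# All four live as versioned, comment-headed CSV files so that parameter
# updates stay diffable.

FORMULATIONS <- c("powder", "liquid_concentrate", "soluble_granule", "soluble_bag")
EQUIPMENT_TYPES <- c("knapsack", "towed_pipe_manual", "tractor_open",
                     "tractor_closed_natural", "tractor_closed_forced",
                     "tractor_closed_charcoal")
BODY_REGIONS <- c("head", "face", "hands", "body", "feet")
WORK_PHASES <- c("mixing_loading", "application", "maintenance")

REFERENCE_FILES <- c(formulation = "formulation_fractions.csv",
                     deposition  = "deposition_factors.csv",
                     protection  = "protection_factors.csv",
                     products    = "products.csv")

#' Directory of the packaged default reference tables
#'
#' @return Path to the `inst/extdata` copy of the reference tables shipped
#'   with the package.
#' @export
default_tables_dir <- function() {
  system.file("extdata", package = "pestrisk", mustWork = TRUE)
}

read_ref_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  strip.white = TRUE)
}

stop_load <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_load("file '%s' is missing column(s): %s", file,
              paste(missing, collapse = ", "))
}

#' Load and validate the reference parameter tables
#'
#' Reads the four delimited text files that parameterise the exposure model:
#'
#' * `formulation_fractions.csv` — mixing-and-loading contact fraction per
#'   formulation type and active-ingredient concentration band
#'   (columns `formulation, band_lo, band_hi, fraction`; fractions are
#'   dimensionless, not percent).
#' * `deposition_factors.csv` — application-phase deposition coefficient per
#'   spraying equipment, in ppm of applied mix (columns `equipment, ppm`).
#' * `protection_factors.csv` — fraction of deposited product retained by
#'   each clothing/PPE item (columns `item, body_region_applicability,
#'   fraction, source`; regions are a semicolon list; `source` flags whether
#'   the value comes from the endorsed reference table or is a package
#'   default).
#' * `products.csv` — product database (columns `product_name, ai_name,
#'   formulation, concentration_pct, gap_g_per_ha, aoel_mg_per_kg,
#'   dermal_absorption_pct`).
#'
#' Every invariant is checked at load time: contact and protection fractions
#' in \[0,1\], deposition coefficients non-negative and strictly decreasing
#' along the equipment ladder, concentration bands partitioning (0,100\],
#' AOEL positive, dermal absorption in \[0,100\] percent, unique product
#' names.
#'
#' @param directory_path Directory containing the four CSV files.
#' @return An object of class `reference_tables` with elements
#'   `formulation`, `deposition`, `protection`, `products` (data frames)
#'   and `directory`.
#' @seealso [formulation_exposure_fraction()], [deposition_factor()],
#'   [protection_factor()], [get_product()], [build_demo_database()]
#' @export
load_reference_tables <- function(directory_path) {
  paths <- file.path(directory_path, REFERENCE_FILES)
  names(paths) <- names(REFERENCE_FILES)
  missing <- REFERENCE_FILES[!file.exists(paths)]
  if (length(missing))
    stop_load("missing reference table file(s) in '%s': %s",
              directory_path, paste(missing, collapse = ", "))

  frm <- read_ref_csv(paths[["formulation"]])
  dep <- read_ref_csv(paths[["deposition"]])
  prt <- read_ref_csv(paths[["protection"]])
  prd <- read_ref_csv(paths[["products"]])

  check_columns(frm, c("formulation", "band_lo", "band_hi", "fraction"),
                REFERENCE_FILES[["formulation"]])
  check_columns(dep, c("equipment", "ppm"), REFERENCE_FILES[["deposition"]])
  check_columns(prt, c("item", "body_region_applicability", "fraction"),
                REFERENCE_FILES[["protection"]])
  check_columns(prd, c("product_name", "ai_name", "formulation",
                       "concentration_pct", "gap_g_per_ha", "aoel_mg_per_kg",
                       "dermal_absorption_pct"),
                REFERENCE_FILES[["products"]])
  if (is.null(prt$source)) prt$source <- "reference"

  # formulation table: fractions in [0,1]; bands partition (0,100] per
  # formulation with half-open-left convention [lo, hi), last band closed.
  bad <- which(!is.finite(frm$fraction) | frm$fraction < 0 | frm$fraction > 1)
  if (length(bad))
    stop_load("formulation_fractions.csv row %d: fraction %s outside [0,1]",
              bad[1], format(frm$fraction[bad[1]]))
  unknown <- setdiff(unique(frm$formulation), FORMULATIONS)
  if (length(unknown))
    stop_load("formulation_fractions.csv: unknown formulation '%s'", unknown[1])
  for (f in unique(frm$formulation)) {
    b <- frm[frm$formulation == f, ]
    b <- b[order(b$band_lo), ]
    if (b$band_lo[1] != 0 || b$band_hi[nrow(b)] != 100 ||
        (nrow(b) > 1 && any(b$band_hi[-nrow(b)] != b$band_lo[-1])))
      stop_load("formulation_fractions.csv: bands for '%s' do not partition (0,100]", f)
  }

  # deposition: non-negative, known equipment, strictly decreasing ladder
  unknown <- setdiff(dep$equipment, EQUIPMENT_TYPES)
  if (length(unknown))
    stop_load("deposition_factors.csv: unknown equipment '%s'", unknown[1])
  bad <- which(!is.finite(dep$ppm) | dep$ppm < 0)
  if (length(bad))
    stop_load("deposition_factors.csv row %d: ppm %s must be >= 0",
              bad[1], format(dep$ppm[bad[1]]))
  ladder <- dep$ppm[match(EQUIPMENT_TYPES, dep$equipment)]
  if (anyNA(ladder))
    stop_load("deposition_factors.csv: missing equipment row(s): %s",
              paste(EQUIPMENT_TYPES[is.na(ladder)], collapse = ", "))
  if (any(diff(ladder) >= 0))
    stop_load("deposition_factors.csv: deposition factors must strictly decrease from knapsack to charcoal-filtered cab")

  # protection: fractions in [0,1], regions resolvable, unique items
  bad <- which(!is.finite(prt$fraction) | prt$fraction < 0 | prt$fraction > 1)
  if (length(bad))
    stop_load("protection_factors.csv row %d (item '%s'), column 'fraction': %s outside [0,1]",
              bad[1], prt$item[bad[1]], format(prt$fraction[bad[1]]))
  if (anyDuplicated(prt$item))
    stop_load("protection_factors.csv: duplicate item '%s'",
              prt$item[duplicated(prt$item)][1])
  regions <- strsplit(prt$body_region_applicability, ";", fixed = TRUE)
  unknown <- setdiff(trimws(unlist(regions)), BODY_REGIONS)
  if (length(unknown))
    stop_load("protection_factors.csv: unknown body region '%s'", unknown[1])

  # products
  if (anyDuplicated(toupper(prd$product_name)))
    stop_load("products.csv: duplicate product name '%s'",
              prd$product_name[duplicated(toupper(prd$product_name))][1])
  unknown <- setdiff(prd$formulation, FORMULATIONS)
  if (length(unknown))
    stop_load("products.csv: unknown formulation '%s'", unknown[1])
  chk <- function(col, ok, msg) {
    bad <- which(!ok(prd[[col]]))
    if (length(bad))
      stop_load("products.csv row %d (product '%s'), column '%s': %s",
                bad[1], prd$product_name[bad[1]], col, msg)
  }
  chk("concentration_pct", function(x) is.finite(x) & x > 0 & x <= 100,
      "must be in (0,100]")
  chk("gap_g_per_ha", function(x) is.finite(x) & x > 0, "must be > 0")
  chk("aoel_mg_per_kg", function(x) is.finite(x) & x > 0, "must be > 0")
  chk("dermal_absorption_pct", function(x) is.finite(x) & x >= 0 & x <= 100,
      "must be in [0,100]")

  structure(list(formulation = frm, deposition = dep, protection = prt,
                 products = prd, directory = normalizePath(directory_path)),
            class = "reference_tables")
}

#' @export
print.reference_tables <- function(x, ...) {
  cat("Reference tables (", x$directory, ")\n", sep = "")
  cat("  formulation bands :", nrow(x$formulation), "rows,",
      length(unique(x$formulation$formulation)), "formulations\n")
  cat("  equipment         :", nrow(x$deposition), "deposition factors\n")
  cat("  PPE items         :", nrow(x$protection), "protection factors\n")
  cat("  products          :", nrow(x$products), "entries\n")
  invisible(x)
}

#' Write reference tables back to delimited text files
#'
#' Inverse of [load_reference_tables()]; reloading the written directory
#' yields identical lookups for every key.
#'
#' @param tables A `reference_tables` object.
#' @param directory_path Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reference_tables <- function(tables, directory_path) {
  stopifnot(inherits(tables, "reference_tables"))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  frames <- list(formulation = tables$formulation,
                 deposition = tables$deposition,
                 protection = tables$protection,
                 products = tables$products)
  out <- character(0)
  for (key in names(frames)) {
    path <- file.path(directory_path, REFERENCE_FILES[[key]])
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(sprintf("# pestrisk reference table '%s' v1", key), con)
    utils::write.csv(frames[[key]], con, row.names = FALSE, quote = FALSE)
    close(con)
    out <- c(out, path)
  }
  invisible(out)
}

# soluble granules share the liquid-concentrate contact row: their
# mixing-and-loading exposure behaviour is equivalent, so the table stores
# one row and the alias is resolved here.
resolve_formulation_row <- function(formulation) {
  if (identical(formulation, "soluble_granule")) "liquid_concentrate" else formulation
}

#' Mixing-and-loading contact fraction for a formulation
#'
#' Returns the fraction of the handled formulation mass that reaches the
#' operator during mixing and loading, banded on the active-ingredient
#' concentration in the formulation. Bands are half-open on the left —
#' \[0,30), \[30,60), \[60,80), \[80,100\] percent — so every concentration
#' in (0,100\] falls in exactly one band. Pre-dosed soluble bags involve no
#' contact with the product and always return 0; soluble granules share the
#' liquid-concentrate row.
#'
#' @param tables A `reference_tables` object.
#' @param formulation One of `"powder"`, `"liquid_concentrate"`,
#'   `"soluble_granule"`, `"soluble_bag"`.
#' @param ai_concentration_pct Active-ingredient mass concentration in the
#'   formulation, g per 100 g, in (0,100\].
#' @return Dimensionless contact fraction in \[0,1\].
#' @export
formulation_exposure_fraction <- function(tables, formulation,
                                          ai_concentration_pct) {
  stopifnot(inherits(tables, "reference_tables"))
  if (!formulation %in% FORMULATIONS)
    stop_load("unknown formulation '%s' (expected one of: %s)", formulation,
              paste(FORMULATIONS, collapse = ", "))
  c_pct <- ai_concentration_pct
  if (!is.finite(c_pct) || c_pct <= 0 || c_pct > 100)
    stop_load("ai_concentration_pct must be in (0,100], got %s", format(c_pct))
  rows <- tables$formulation[tables$formulation$formulation ==
                               resolve_formulation_row(formulation), ]
  if (!nrow(rows))
    stop_load("no contact-fraction rows for formulation '%s'", formulation)
  hit <- rows$band_lo <= c_pct & (c_pct < rows$band_hi | rows$band_hi == 100)
  rows$fraction[which(hit)[1]]
}

#' Application-phase deposition factor for a spraying equipment
#'
#' Returns the fraction of applied spray mix deposited on the operator, in
#' ppm (mg of mix on the operator per kg of mix applied), for the given
#' equipment, scaled by the configurable crop-height and spray-pressure
#' multipliers (both default to 1, i.e. no effect).
#'
#' @param tables A `reference_tables` object.
#' @param equipment One of `"knapsack"`, `"towed_pipe_manual"`,
#'   `"tractor_open"`, `"tractor_closed_natural"`,
#'   `"tractor_closed_forced"`, `"tractor_closed_charcoal"`.
#' @param crop_height `"low"` or `"high"`.
#' @param pressure_bar Spray pressure in bar (`NULL` for the default band).
#' @param settings An [engine_settings()] object supplying the multipliers.
#' @return Deposition factor in ppm of applied mix.
#' @export
deposition_factor <- function(tables, equipment, crop_height = "low",
                              pressure_bar = NULL,
                              settings = engine_settings()) {
  stopifnot(inherits(tables, "reference_tables"))
  if (!equipment %in% EQUIPMENT_TYPES)
    stop_load("unknown equipment '%s' (expected one of: %s)", equipment,
              paste(EQUIPMENT_TYPES, collapse = ", "))
  if (!crop_height %in% c("low", "high"))
    stop_load("crop_height must be 'low' or 'high', got '%s'", crop_height)
  if (!is.null(pressure_bar) && (!is.finite(pressure_bar) || pressure_bar < 0))
    stop_load("pressure_bar must be >= 0, got %s", format(pressure_bar))
  base <- tables$deposition$ppm[tables$deposition$equipment == equipment]
  base * crop_height_multiplier(settings, crop_height) *
    pressure_multiplier(settings, pressure_bar)
}

#' Protection factor of a clothing/PPE item
#'
#' The protection factor is the fraction of deposited product the item
#' retains, i.e. keeps off the skin; its complement to one passes through.
#' `"none"` (no protection) returns 0.
#'
#' @param tables A `reference_tables` object.
#' @param item PPE item identifier, or `"none"`.
#' @return Protection fraction in \[0,1\].
#' @export
protection_factor <- function(tables, item) {
  stopifnot(inherits(tables, "reference_tables"))
  if (identical(item, "none")) return(0)
  idx <- match(item, tables$protection$item)
  if (is.na(idx))
    stop_load("unknown PPE item '%s' (valid: none, %s)", item,
              paste(tables$protection$item, collapse = ", "))
  tables$protection$fraction[idx]
}

ppe_source <- function(tables, item) {
  if (identical(item, "none")) return("none")
  tables$protection$source[match(item, tables$protection$item)]
}

#' PPE items applicable to a body region
#'
#' @param tables A `reference_tables` object.
#' @param region One of `"head"`, `"face"`, `"hands"`, `"body"`, `"feet"`.
#' @return Character vector of item identifiers (excluding `"none"`).
#' @export
items_for_region <- function(tables, region) {
  stopifnot(region %in% BODY_REGIONS)
  regions <- strsplit(tables$protection$body_region_applicability, ";",
                      fixed = TRUE)
  tables$protection$item[vapply(regions,
                                function(r) region %in% trimws(r), logical(1))]
}

#' Look up a product by commercial name
#'
#' Lookup is case-insensitive. An unknown name raises an error listing near
#' matches from the database.
#'
#' @param tables A `reference_tables` object.
#' @param name Commercial product name.
#' @return A one-row list of class `product` with fields `name`, `ai_name`,
#'   `formulation`, `concentration_pct`, `gap_g_per_ha`, `aoel_mg_per_kg`,
#'   `dermal_absorption` (as a fraction in \[0,1\]).
#' @export
get_product <- function(tables, name) {
  stopifnot(inherits(tables, "reference_tables"))
  idx <- match(toupper(name), toupper(tables$products$product_name))
  if (is.na(idx)) {
    near <- if (!nzchar(name)) character(0) else
      tables$products$product_name[
        agrep(name, tables$products$product_name, ignore.case = TRUE,
              max.distance = 0.3)]
    hint <- if (length(near)) paste0("; did you mean: ",
                                     paste(near, collapse = ", "), "?") else ""
    stop_load("product '%s' not found in database%s", name, hint)
  }
  row <- tables$products[idx, ]
  structure(list(name = row$product_name,
                 ai_name = row$ai_name,
                 formulation = row$formulation,
                 concentration_pct = as.numeric(row$concentration_pct),
                 gap_g_per_ha = as.numeric(row$gap_g_per_ha),
                 aoel_mg_per_kg = as.numeric(row$aoel_mg_per_kg),
                 dermal_absorption = as.numeric(row$dermal_absorption_pct) / 100),
            class = "product")
}

#' @export
print.product <- function(x, ...) {
  cat(sprintf("%s (%s, %s)\n", x$name, x$ai_name, x$formulation))
  cat(sprintf("  AI concentration : %g g/100 g\n", x$concentration_pct))
  cat(sprintf("  GAP rate         : %g g formulation/ha\n", x$gap_g_per_ha))
  cat(sprintf("  AOEL             : %g mg/kg bw/day\n", x$aoel_mg_per_kg))
  cat(sprintf("  dermal absorption: %g%%\n", 100 * x$dermal_absorption))
  invisible(x)
}
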