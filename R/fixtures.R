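# Packaged demo database and the deterministic random-scenario generator.
# Everything here is written literally so regenerated files are
# byte-identical across runs.

DEMO_FORMULATION_CSV <- c(
  "# pestrisk reference table 'formulation' v1",
  "# Mixing-and-loading contact fraction per formulation and AI-concentration",
  "# band (percent, half-open-left: [0,30) [30,60) [60,80) [80,100]).",
  "# Fractions are dimensionless (table prints percent; 0.045% -> 0.00045).",
  "# Note: the endorsed table ranks liquid concentrate above powder even",
  "# though narrative accounts rank powders as the most contaminating form;",
  "# the printed table values are authoritative here.",
  "# Soluble granules share the liquid_concentrate row (alias, not a row).",
  "formulation,band_lo,band_hi,fraction",
  "soluble_bag,0,30,0",
  "soluble_bag,30,60,0",
  "soluble_bag,60,80,0",
  "soluble_bag,80,100,0",
  "liquid_concentrate,0,30,0.0003",
  "liquid_concentrate,30,60,0.00045",
  "liquid_concentrate,60,80,0.0007",
  "liquid_concentrate,80,100,0.0009",
  "powder,0,30,0.00003",
  "powder,30,60,0.00005",
  "powder,60,80,0.00007",
  "powder,80,100,0.00009")

DEMO_DEPOSITION_CSV <- c(
  "# pestrisk reference table 'deposition' v1",
  "# Fraction of applied spray mix deposited on the operator, in ppm",
  "# (mg mix on operator per kg mix applied; 1 ppm = 0.1 mL/hL).",
  "# The charcoal-filtered cab is the forced-ventilation value reduced by",
  "# 99%: 0.1 x (1 - 0.99) = 0.001 ppm.",
  "equipment,ppm",
  "knapsack,1000",
  "towed_pipe_manual,100",
  "tractor_open,10",
  "tractor_closed_natural,1",
  "tractor_closed_forced,0.1",
  "tractor_closed_charcoal,0.001")

DEMO_PROTECTION_CSV <- c(
  "# pestrisk reference table 'protection' v1",
  "# Fraction of deposited product retained by the item (kept off the skin).",
  "# source=reference: endorsed clothing table; source=default: package",
  "# defaults for item classes the endorsed table does not price, chosen",
  "# consistently with its generic-vs-technical span and flagged in audits.",
  "item,body_region_applicability,fraction,source",
  "underwear,body,0.50,reference",
  "generic_clothes,body,0.70,reference",
  "cotton_coverall,body,0.90,reference",
  "nonwoven_coverall,body,0.90,reference",
  "hazmat_coverall,body,0.99,reference",
  "generic_gloves,hands,0.90,default",
  "specific_gloves,hands,0.99,default",
  "headdress,head,0.90,default",
  "mask,face,0.90,default",
  "shoes,feet,0.70,default",
  "boots,feet,0.99,default")

DEMO_PRODUCTS_CSV <- c(
  "# pestrisk reference table 'products' v1",
  "# Demonstration active-ingredient database (16 entries). Row 1 is the",
  "# worked exercise product; all DEMO- entries are synthetic and must not",
  "# be mistaken for real authorization records.",
  "product_name,ai_name,formulation,concentration_pct,gap_g_per_ha,aoel_mg_per_kg,dermal_absorption_pct",
  "KILLER,ACTIVOL,powder,50,100,0.05,5",
  "DEMO-FUNGON,DEMO-AZOLINE,powder,80,500,0.02,10",
  "DEMO-DUSTIT,DEMO-CARBAXIM,powder,25,300,0.001,2",
  "DEMO-POWDRIX,DEMO-THIOPRAM,powder,65,800,0.2,8",
  "DEMO-LIQUIFOS,DEMO-FOSETHION,liquid_concentrate,40,1500,0.005,20",
  "DEMO-HERBAX,DEMO-GLUFOTRIN,liquid_concentrate,36,2000,0.1,10",
  "DEMO-OLEOGARD,DEMO-OLEANIL,liquid_concentrate,15,1200,0.05,25",
  "DEMO-VINCLEAR,DEMO-PYRALOX,liquid_concentrate,70,600,0.5,5",
  "DEMO-MAXITOX,DEMO-DIMETHRIN,liquid_concentrate,90,250,0.01,30",
  "DEMO-GRANUFLOW,DEMO-CUPRONEX,soluble_granule,70,3000,1,1",
  "DEMO-SOLUGRAN,DEMO-METIRAM,soluble_granule,55,1800,0.08,4",
  "DEMO-PELLETIX,DEMO-ZOXAFEN,soluble_granule,30,900,0.3,6",
  "DEMO-SAFEBAG,DEMO-ACARIDON,soluble_bag,85,400,0.01,15",
  "DEMO-BAGPRO,DEMO-FLURAZEN,soluble_bag,50,700,0.04,12",
  "DEMO-ENVELOPE,DEMO-TEBUMOL,soluble_bag,95,200,0.002,18",
  "DEMO-MIXSAFE,DEMO-PROPIZOL,soluble_bag,20,1000,0.6,9")

DEMO_CROP_HEIGHTS_CSV <- c(
  "# pestrisk crop-height lookup v1 (editable)",
  "# low: spray directed downwards (herbicides on field crops);",
  "# high: spray directed upwards (bush and tree crops).",
  "crop,height",
  "cereals,low", "wheat,low", "barley,low", "maize,low", "rice,low",
  "potato,low", "sugar beet,low", "soybean,low", "tomato,low",
  "vineyard,high", "grape,high", "olive,high", "apple,high", "pear,high",
  "peach,high", "citrus,high", "orchard,high")

#' Write the packaged demonstration database
#'
#' Writes the four reference CSVs (formulation contact fractions, equipment
#' deposition coefficients, PPE protection factors, 16-entry product
#' database) plus the crop-height lookup into `out_dir`. The content is
#' literal and deterministic: regenerated files are byte-identical across
#' runs. Synthetic product entries carry a `DEMO-` prefix.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
build_demo_database <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  content <- list(formulation_fractions.csv = DEMO_FORMULATION_CSV,
                  deposition_factors.csv = DEMO_DEPOSITION_CSV,
                  protection_factors.csv = DEMO_PROTECTION_CSV,
                  products.csv = DEMO_PRODUCTS_CSV,
                  crop_heights.csv = DEMO_CROP_HEIGHTS_CSV)
  paths <- file.path(out_dir, names(content))
  for (i in seq_along(content)) {
    con <- file(paths[i], "wb")  # fixed LF endings for byte identity
    writeLines(content[[i]], con, sep = "\n")
    close(con)
  }
  invisible(paths)
}

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random but always-valid scenario
#'
#' Deterministic per seed. Samples the treated area in \[0.1, 100\] ha, any
#' product from the database, any equipment, any PPE combination (items
#' applicable to each region, or none), spray volume in \[1, 20\] hL/ha,
#' tank in \[100, 3000\] L, pressure in \[1, 10\] bar, low or high crop,
#' and skips mixing-and-loading with probability 0.1. Body weight is fixed
#' at the 60 kg convention. The result always passes [validate_scenario()]
#' without error-severity findings.
#'
#' @param seed Integer seed.
#' @param tables A `reference_tables` object.
#' @return A `scenario` object.
#' @export
generate_random_scenario <- function(seed, tables) {
  stopifnot(inherits(tables, "reference_tables"))
  with_local_seed(seed, {
    ppe <- lapply(WORK_PHASES, function(phase) {
      sel <- lapply(BODY_REGIONS, function(region) {
        sample(c("none", items_for_region(tables, region)), 1)
      })
      names(sel) <- BODY_REGIONS
      sel
    })
    names(ppe) <- WORK_PHASES
    structure(list(
      crop = list(name = "synthetic", height = sample(c("low", "high"), 1)),
      pest = "synthetic",
      area_ha = stats::runif(1, 0.1, 100),
      product_name = sample(tables$products$product_name, 1),
      application = list(
        spray_volume_hl_per_ha = stats::runif(1, 1, 20),
        tank_volume_l = stats::runif(1, 100, 3000),
        pressure_bar = stats::runif(1, 1, 10),
        equipment = sample(EQUIPMENT_TYPES, 1)),
      ppe = ppe,
      body_weight_kg = DEFAULT_BODY_WEIGHT_KG,
      skip_mixing_loading = stats::runif(1) < 0.1),
      class = "scenario")
  })
}
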