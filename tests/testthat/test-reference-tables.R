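test_that("packaged tables load with the documented shape", {
  tb <- demo_tables()
  expect_s3_class(tb, "reference_tables")
  # every formulation answers in every band (the granule alias included)
  for (f in c("powder", "liquid_concentrate", "soluble_granule", "soluble_bag"))
    for (conc in c(15, 45, 70, 90))
      expect_no_error(formulation_exposure_fraction(tb, f, conc))
  expect_equal(nrow(tb$deposition), 6)
  expect_gte(sum(grepl("body", tb$protection$body_region_applicability)), 5)
  expect_equal(nrow(tb$products), 16)
})

test_that("loader errors name the missing files and the offending cell", {
  empty <- withr::local_tempdir()
  err <- expect_error(load_reference_tables(empty), "missing reference table")
  for (f in c("formulation_fractions.csv", "deposition_factors.csv",
              "protection_factors.csv", "products.csv"))
    expect_match(conditionMessage(err), f, fixed = TRUE)

  dir <- edited_tables_dir(function(d) {
    path <- file.path(d, "protection_factors.csv")
    txt <- sub("hazmat_coverall,body,0.99", "hazmat_coverall,body,1.5",
               readLines(path), fixed = TRUE)
    writeLines(txt, path)
  })
  expect_error(load_reference_tables(dir),
               "hazmat_coverall.*fraction.*1\\.5 outside")

  dir <- edited_tables_dir(function(d) {
    path <- file.path(d, "products.csv")
    writeLines(c(readLines(path), "killer,OTHER,powder,10,10,0.1,5"), path)
  })
  expect_error(load_reference_tables(dir), "duplicate product name")
})

test_that("concentration banding is half-open-left with no boundary gaps", {
  tb <- demo_tables()
  # boundaries 30/60/80 belong to the upper band
  expect_equal(formulation_exposure_fraction(tb, "liquid_concentrate", 30), 0.00045)
  expect_equal(formulation_exposure_fraction(tb, "liquid_concentrate", 60), 0.0007)
  expect_equal(formulation_exposure_fraction(tb, "liquid_concentrate", 80), 0.0009)
  expect_equal(formulation_exposure_fraction(tb, "powder", 100), 0.00009)
  # soluble granules share the liquid-concentrate row; bags are always zero
  for (conc in c(5, 30, 59.999, 80, 100)) {
    expect_equal(formulation_exposure_fraction(tb, "soluble_granule", conc),
                 formulation_exposure_fraction(tb, "liquid_concentrate", conc))
    expect_identical(formulation_exposure_fraction(tb, "soluble_bag", conc), 0)
  }
  expect_error(formulation_exposure_fraction(tb, "gel", 50), "unknown formulation")
  expect_error(formulation_exposure_fraction(tb, "powder", 0), "in \\(0,100\\]")
  expect_error(formulation_exposure_fraction(tb, "powder", 101), "in \\(0,100\\]")
})

test_that("banded fraction is non-decreasing in concentration", {
  tb <- demo_tables()
  for (f in c("liquid_concentrate", "powder")) {
    fracs <- vapply(seq(0.5, 100, by = 0.5), function(conc)
      formulation_exposure_fraction(tb, f, conc), numeric(1))
    expect_true(all(diff(fracs) >= 0))
  }
})

test_that("deposition ladder decreases strictly and rejects bad input", {
  tb <- demo_tables()
  ladder <- vapply(c("knapsack", "towed_pipe_manual", "tractor_open",
                     "tractor_closed_natural", "tractor_closed_forced",
                     "tractor_closed_charcoal"),
                   function(e) deposition_factor(tb, e), numeric(1))
  expect_true(all(diff(ladder) < 0))
  expect_error(deposition_factor(tb, "drone"), "unknown equipment")
  expect_error(deposition_factor(tb, "knapsack", pressure_bar = -1), ">= 0")
  # multipliers act multiplicatively on the base value
  st <- engine_settings(crop_height_multipliers = c(low = 1, high = 2),
                        pressure_multipliers = data.frame(lo = c(0, 5),
                                                          hi = c(5, Inf),
                                                          multiplier = c(1, 3)))
  expect_equal(deposition_factor(tb, "tractor_open", "high", 7, st), 10 * 2 * 3)
})

test_that("protection lookups handle none and unknown items", {
  tb <- demo_tables()
  expect_identical(protection_factor(tb, "none"), 0)
  err <- expect_error(protection_factor(tb, "cape"), "unknown PPE item")
  expect_match(conditionMessage(err), "hazmat_coverall")
  expect_setequal(items_for_region(tb, "hands"),
                  c("generic_gloves", "specific_gloves"))
})

test_that("product lookup is case-insensitive and suggests near matches", {
  tb <- demo_tables()
  p <- get_product(tb, "killer")
  expect_identical(p$name, "KILLER")
  expect_identical(p$ai_name, "ACTIVOL")
  expect_error(get_product(tb, ""), "not found")
  expect_error(get_product(tb, "KILLLER"), "did you mean.*KILLER")
})

test_that("write/reload round-trip preserves every lookup", {
  tb <- demo_tables()
  dir <- withr::local_tempdir()
  write_reference_tables(tb, dir)
  tb2 <- load_reference_tables(dir)
  for (f in c("powder", "liquid_concentrate", "soluble_granule", "soluble_bag"))
    for (conc in c(10, 30, 45, 60, 70, 80, 95, 100))
      expect_identical(formulation_exposure_fraction(tb2, f, conc),
                       formulation_exposure_fraction(tb, f, conc))
  for (e in tb$deposition$equipment)
    expect_identical(deposition_factor(tb2, e), deposition_factor(tb, e))
  for (item in tb$protection$item)
    expect_identical(protection_factor(tb2, item), protection_factor(tb, item))
  expect_identical(tb2$products, tb$products)
})
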