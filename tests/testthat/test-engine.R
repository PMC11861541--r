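test_that("applied AI mass and tank-load count follow the label arithmetic", {
  tb <- demo_tables()
  killer <- get_product(tb, "KILLER")
  expect_equal(ai_mass_applied(killer, 10), 500000)   # 100 g/ha x 10 ha x 50%
  expect_equal(ai_mass_applied(killer, 1e-9), 5e-5 * 1)
  pure <- killer; pure$concentration_pct <- 100
  expect_equal(ai_mass_applied(pure, 1), 100000)

  expect_identical(n_tank_loads(10, 10, 1000), 10L)
  expect_identical(n_tank_loads(9.5, 1, 1000), 1L)
  expect_identical(n_tank_loads(10, 10, 999), 11L)
  expect_identical(n_tank_loads(0.1, 0.1, 3000), 1L)  # floor of one load
})

test_that("mixing-and-loading ledger matches the hand calculation", {
  tb <- demo_tables()
  sc <- killer_scenario()
  ml <- exposure_mixing_loading(sc, tb)
  # 1000 g x 1000 mg/g x 5e-5 x 0.5 -> 25 mg AI on bare hands
  expect_equal(ml$potential_exposure_mg, 25)
  expect_equal(ml$skin_loading_mg, 25)
  expect_equal(ml$absorbed_mg, 1.25)

  gloved <- with_ppe(sc, "mixing_loading", "hands", "specific_gloves")
  expect_equal(exposure_mixing_loading(gloved, tb)$absorbed_mg, 1.25 * 0.01)

  bag <- sc; bag$product_name <- "DEMO-SAFEBAG"
  z <- exposure_mixing_loading(bag, tb)
  expect_equal(z$potential_exposure_mg, 0)
  expect_equal(z$absorbed_mg, 0)
  expect_false(z$excluded)

  skip <- sc; skip$skip_mixing_loading <- TRUE
  z <- exposure_mixing_loading(skip, tb)
  expect_equal(z$absorbed_mg, 0)
  expect_true(z$excluded)
})

test_that("application ledger splits the ppm deposit over body regions", {
  tb <- demo_tables()
  sc <- killer_scenario()
  app <- exposure_application(sc, tb)
  expect_equal(app$potential_exposure_mg, 5)   # 5e5 mg x 10 ppm x 1e-6
  expect_equal(app$absorbed_mg, 0.25)

  suited <- with_ppe(sc, "application", "body", "hazmat_coverall")
  expect_equal(exposure_application(suited, tb)$skin_loading_mg,
               5 * (1 - 0.60 * 0.99))

  # zero deposition (hypothetical sealed equipment) zeroes the whole ledger
  dir <- edited_tables_dir(function(d) {
    path <- file.path(d, "deposition_factors.csv")
    writeLines(sub("tractor_closed_charcoal,0.001", "tractor_closed_charcoal,0",
                   readLines(path), fixed = TRUE), path)
  })
  sealed <- sc
  sealed$application$equipment <- "tractor_closed_charcoal"
  z <- exposure_application(sealed, load_reference_tables(dir))
  expect_equal(z$potential_exposure_mg, 0)
  expect_equal(z$absorbed_mg, 0)
})

test_that("maintenance ledger uses the dilute-mix concentration", {
  tb <- demo_tables()
  sc <- killer_scenario()
  man <- exposure_maintenance(sc, tb)
  # 1000 kg handled x 3e-4 x 50 mg AI/kg mix
  expect_equal(man$potential_exposure_mg, 15)
  expect_equal(man$absorbed_mg, 0.75)

  gloved <- with_ppe(sc, "maintenance", "hands", "generic_gloves")
  expect_equal(exposure_maintenance(gloved, tb)$absorbed_mg, 0.075)

  dilute <- sc
  dilute$application$spray_volume_hl_per_ha <- 20
  expect_equal(exposure_maintenance(dilute, tb)$potential_exposure_mg, 7.5)

  st <- engine_settings(maintenance_handled_mass_kg = 100)
  expect_equal(exposure_maintenance(sc, tb, st)$potential_exposure_mg, 1.5)
})

test_that("full assessment reproduces the reference scenario end to end", {
  tb <- demo_tables()
  res <- assess_scenario(killer_scenario(), tb)
  expect_equal(vapply(res$phases, `[[`, numeric(1), "absorbed_mg"),
               c(mixing_loading = 1.25, application = 0.25, maintenance = 0.75))
  expect_equal(res$total_absorbed_mg, 2.25)
  expect_equal(res$acceptable_dose_mg, 3.0)
  expect_equal(res$risk_percent, 75)
  expect_identical(res$tier, "yellow")
  expect_identical(res$n_tank_loads, 10L)
  expect_identical(res$audit$product$name, "KILLER")
  expect_true(any(res$warnings$severity == "warning"))

  protected <- killer_scenario("
ppe:
  mixing_loading: {hands: specific_gloves}
  application: {face: mask, head: headdress, hands: specific_gloves, body: hazmat_coverall, feet: boots}
  maintenance: {hands: specific_gloves}
")
  expect_lt(assess_scenario(protected, tb)$risk_percent, 75)

  bad <- killer_scenario()
  bad$product_name <- "NOSUCH"
  expect_error(assess_scenario(bad, tb), "invalid scenario.*product.name")
})

test_that("limit cases: huge AOEL goes green, zero absorption zero risk", {
  sc <- killer_scenario()
  dir <- edited_tables_dir(function(d) {
    path <- file.path(d, "products.csv")
    txt <- sub("KILLER,ACTIVOL,powder,50,100,0.05,5",
               "KILLER,ACTIVOL,powder,50,100,1e9,5", readLines(path),
               fixed = TRUE)
    writeLines(txt, path)
  })
  res <- assess_scenario(sc, load_reference_tables(dir))
  expect_lt(res$risk_percent, 1e-6)
  expect_identical(res$tier, "green")

  dir <- edited_tables_dir(function(d) {
    path <- file.path(d, "products.csv")
    txt <- sub("KILLER,ACTIVOL,powder,50,100,0.05,5",
               "KILLER,ACTIVOL,powder,50,100,0.05,0", readLines(path),
               fixed = TRUE)
    writeLines(txt, path)
  })
  expect_equal(assess_scenario(sc, load_reference_tables(dir))$risk_percent, 0)
})

test_that("tier classification respects the threshold conventions", {
  expect_identical(classify_tier(0), "green")
  expect_identical(classify_tier(49.999), "green")
  expect_identical(classify_tier(50), "yellow")    # boundary owned by yellow
  expect_identical(classify_tier(75), "yellow")
  expect_identical(classify_tier(100), "yellow")   # 100% of AOEL still borderline
  expect_identical(classify_tier(101), "red")
  st <- engine_settings(tier_green_lt = 10, tier_red_gt = 20)
  expect_identical(classify_tier(15, st), "yellow")
  expect_error(engine_settings(tier_green_lt = 30, tier_red_gt = 20))
})

test_that("settings files override defaults key by key", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("
tier_green_lt: 25
maintenance_contact_fraction: 0.001
crop_height_multipliers: {low: 1, high: 2.5}
pressure_multipliers:
  - {lo: 0, hi: 5, multiplier: 1}
  - {lo: 5, multiplier: 1.8}
", path)
  st <- read_engine_settings(path)
  expect_equal(st$tier_green_lt, 25)
  expect_equal(st$tier_red_gt, 100)  # untouched default
  expect_equal(st$maintenance_contact_fraction, 0.001)
  expect_identical(classify_tier(30, st), "yellow")
  tb <- demo_tables()
  expect_equal(deposition_factor(tb, "tractor_open", "high", 7, st),
               10 * 2.5 * 1.8)
  expect_error(read_engine_settings(file.path(tempdir(), "nope.yaml")),
               "not found")
})

test_that("mass ledger, linearity and ppm identities hold on random scenarios", {
  tb <- demo_tables()
  st <- engine_settings()
  for (seed in 1:60) {
    sc <- generate_random_scenario(seed, tb)
    res <- assess_scenario(sc, tb, st)
    for (p in res$phases) {
      expect_identical(p$retained_by_ppe_mg,
                       p$potential_exposure_mg - p$skin_loading_mg)
      expect_gte(p$skin_loading_mg, 0)
      expect_lte(p$skin_loading_mg, p$potential_exposure_mg * (1 + 1e-12))
    }
    # application potential / applied AI mass == deposition ppm x 1e-6
    prod <- get_product(tb, sc$product_name)
    expect_equal(res$phases$application$potential_exposure_mg /
                   ai_mass_applied(prod, sc$area_ha),
                 deposition_factor(tb, sc$application$equipment,
                                   sc$crop$height,
                                   sc$application$pressure_bar, st) * 1e-6,
                 tolerance = 1e-12)
    # M&L and APP absorbed doses scale exactly linearly with area
    doubled <- sc; doubled$area_ha <- 2 * sc$area_ha
    res2 <- assess_scenario(doubled, tb, st)
    expect_equal(res2$phases$mixing_loading$absorbed_mg,
                 2 * res$phases$mixing_loading$absorbed_mg, tolerance = 1e-12)
    expect_equal(res2$phases$application$absorbed_mg,
                 2 * res$phases$application$absorbed_mg, tolerance = 1e-12)
    expect_gte(res2$risk_percent, res$risk_percent * (1 - 1e-12))
  }
})

test_that("better PPE or gentler equipment never increases risk", {
  tb <- demo_tables()
  regions <- c("head", "face", "hands", "body", "feet")
  phases <- c("mixing_loading", "application", "maintenance")
  equipment_ladder <- tb$deposition$equipment[order(-tb$deposition$ppm)]
  for (seed in 61:120) {
    sc <- generate_random_scenario(seed, tb)
    base <- assess_scenario(sc, tb)$risk_percent
    phase <- phases[1 + seed %% 3]
    region <- regions[1 + seed %% 5]
    best <- items_for_region(tb, region)
    best <- best[which.max(vapply(best, protection_factor, numeric(1),
                                  tables = tb))]
    up <- with_ppe(sc, phase, region, best)
    expect_lte(assess_scenario(up, tb)$risk_percent, base * (1 + 1e-12))

    idx <- match(sc$application$equipment, equipment_ladder)
    if (idx < length(equipment_ladder)) {
      gentler <- sc
      gentler$application$equipment <- equipment_ladder[idx + 1]
      expect_lte(assess_scenario(gentler, tb)$risk_percent, base * (1 + 1e-12))
    }
  }
})

test_that("engine matches the independent closed-form oracle", {
  tb <- demo_tables()
  st <- engine_settings()
  for (seed in 1:50) {
    sc <- generate_random_scenario(seed, tb)
    res <- assess_scenario(sc, tb, st)
    exp <- oracle_assess(sc, tb, st)
    expect_equal(res$total_absorbed_mg, exp$total, tolerance = 1e-12)
    expect_equal(res$risk_percent, exp$risk, tolerance = 1e-12)
  }
  # also under non-default settings (multipliers, handled mass, weights)
  st2 <- engine_settings(
    body_region_weights = c(head = 0.1, face = 0.1, hands = 0.3, body = 0.4,
                            feet = 0.1),
    maintenance_contact_fraction = 1e-3,
    maintenance_handled_mass_kg = 250,
    crop_height_multipliers = c(low = 0.8, high = 1.6),
    pressure_multipliers = data.frame(lo = c(0, 5), hi = c(5, Inf),
                                      multiplier = c(0.9, 1.4)))
  for (seed in 121:150) {
    sc <- generate_random_scenario(seed, tb)
    res <- assess_scenario(sc, tb, st2)
    exp <- oracle_assess(sc, tb, st2)
    expect_equal(res$risk_percent, exp$risk, tolerance = 1e-12)
  }
})
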