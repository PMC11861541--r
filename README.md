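# pestrisk

Preventive occupational risk assessment for agricultural pesticide use.

Farmers and farm employers are legally required to assess chemical risk
*before* a pesticide treatment, but the established operator-exposure models
assume laboratory measurements and expert users. `pestrisk` works from what
the farmer already knows at planning time — crop, treated area, product
label data, spray equipment, and the personal protective equipment (PPE)
worn in each work phase — and returns the operator's predicted absorbed dose
of active ingredient as a percentage of the Acceptable Operator Exposure
Level (AOEL), with a green / yellow / red verdict.

## The model

Three work phases are assessed (re-entry is out of scope): **mixing and
loading** of the concentrate, **application** of the spray, and
**maintenance/cleaning** of equipment wetted with dilute mix. Each phase
follows the dose chain common to the German, UK-POEM and EFSA operator
models:

```
dose [mg AI] = mass handled or applied × contact/deposition fraction
               × (1 − PF) × dermal absorption
risk R [%]   = 100 × Σ phase doses / (AOEL × body weight)
```

* the mixing-and-loading contact fraction depends on the formulation type
  (powder, liquid concentrate, soluble granules, pre-dosed soluble bags —
  the last involve no contact at all) and the AI concentration band;
* the application deposition factor depends on the equipment, from
  1000 ppm of applied mix for a knapsack down to 0.001 ppm for a sealed
  charcoal-filtered tractor cab, split over five body regions;
* each region is shielded by its PPE item's protection factor `PF` (the
  fraction the barrier retains, e.g. 0.99 for a HazMat coverall);
* maintenance mirrors mixing and loading, but with the dilute solution.

All parameters live in versioned, diffable CSV tables packaged under
`inst/extdata/`; every constant the tables do not fix is a documented,
overridable `engine_settings()` default. See the methods vignette
(`vignettes/pesticide-risk-model.Rmd`) for assumptions and design choices.

## Worked example

The packaged database ships a worked exercise product: `KILLER`, a 50%
powder of the active ingredient `ACTIVOL` (GAP 100 g/ha, AOEL 0.05 mg/kg
bw/day, dermal absorption 5%). Treating 10 ha of olives at 10 hL/ha with a
1000 L tank from an open tractor, with no PPE:

```r
library(pestrisk)
tables   <- load_reference_tables(default_tables_dir())
scenario <- parse_scenario("
crop: {name: olive, height: high}
area_ha: 10
product: {name: KILLER}
application:
  spray_volume_hl_per_ha: 10
  tank_volume_l: 1000
  pressure_bar: 3
  equipment: tractor_open
")
assess_scenario(scenario, tables)
#> ⚠️ risk index: 75% of AOEL (tier yellow)
#>   absorbed 2.25 mg vs acceptable 3 mg/day; 10 tank load(s)
#>   mixing_loading  absorbed 1.25 mg (potential 25 mg)
#>   application     absorbed 0.25 mg (potential 5 mg)
#>   maintenance     absorbed 0.75 mg (potential 15 mg)
```

Reading: of the 500 g of active ingredient applied, 2.25 mg would cross the
operator's skin in a day — 75% of the acceptable dose (0.05 mg/kg × 60 kg =
3 mg), a borderline (yellow) condition. Handling the bare concentrate
dominates, so the what-if search finds a one-move fix:

```r
suggest_improvements(scenario, tables, max_changes = 1)
#> Baseline: 75% of AOEL (tier yellow)
#>  1. [green, 33.8%] ppe.mixing_loading.hands -> specific_gloves
#>  2. [green, 37.5%] ppe.mixing_loading.hands -> generic_gloves
```

`render_report(result, scenario, "markdown")` produces the printable
assessment document (per-phase ledger, warnings, full parameter audit);
`"json"` produces the machine-readable equivalent.

A thin CLI wraps the same functions (exit codes encode the tier — 0 green,
2 yellow, 3 red, 1 error):

```sh
inst/cli/pestrisk assess --scenario plan.yaml
inst/cli/pestrisk list-products
inst/cli/pestrisk what-if --scenario plan.yaml --max-changes 2
```

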