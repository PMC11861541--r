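---
title: "The pestrisk exposure model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pestrisk exposure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestrisk)
```

## The problem

Before a pesticide treatment takes place, an employer must document that the
operator's exposure will stay within acceptable bounds. The regulatory anchor
is the Acceptable Operator Exposure Level (AOEL): a health-based limit on the
daily absorbed dose of an active ingredient, in mg per kg of operator body
weight, fixed at product authorization. pestrisk estimates the operator's
absorbed dermal dose over one workday *preventively* — from declared plans,
not measurements — and expresses it as a percentage of `AOEL × body weight`,
with a three-tier verdict (green: safe; yellow: borderline; red: application
unadvisable).

A workday is decomposed into three phases, each with its own exposure
mechanism and its own PPE selection:

1. **Mixing and loading (M&L)** — the operator handles the *concentrated*
   formulation while charging the spray tank.
2. **Application (APP)** — a fraction of the sprayed mix deposits on the
   operator.
3. **Maintenance and cleaning (MAN)** — the operator handles equipment wetted
   with the *dilute* spray solution.

Re-entry into the treated field is a distinct fourth exposure phase and is
deliberately out of scope, as are inhalation exposure, tank mixes of several
products, multi-day aggregation and bystander/environmental endpoints.

## The dose chain

All three phases share one structure, common to the established operator
exposure models (German model, UK POEM, EFSA calculator):

$$D = M \cdot f_{\text{contact}} \cdot (1 - PF) \cdot f_{\text{derm}}$$

where $M$ is the mass handled or applied, $f_{\text{contact}}$ a
dimensionless contact or deposition fraction, $PF$ the protection factor of
the PPE item covering the contaminated region (the fraction the barrier
retains), and $f_{\text{derm}}$ the dermal absorption coefficient of the
active ingredient. The risk index is

$$R = 100 \cdot \frac{\sum_{\text{phases}} D}{\text{AOEL} \cdot BW} \quad [\%].$$

Phase by phase:

* **M&L** — handled mass is the formulation needed for the treatment
  (`GAP rate [g/ha] × area [ha]`). The contact fraction comes from the
  formulation table, banded on the AI concentration; multiplying by
  `concentration/100` converts contacted formulation to active ingredient.
  Contact is assigned entirely to the hands (the phase is manual), so only
  the M&L gloves attenuate it. If the product comes in pre-dosed soluble
  bags, or loading is done at a loading station (`skip_mixing_loading`),
  the whole ledger is zero — and the report shows the phase as *excluded*
  rather than computed-zero in the latter case.
* **APP** — the deposition factor (ppm) is a mass ratio of mix-on-operator
  to mix-applied; since the AI travels with the mix, the same ratio applies
  to AI mass, so potential exposure is `applied AI mass × ppm × 1e-6` and
  the spray dilution cancels. The deposit is split over the five PPE
  regions (head, face, hands, body, feet) by the configurable
  `body_region_weights`, each attenuated by its item's `1 − PF`.
* **MAN** — mirrors M&L but with dilute solution: handled mass defaults to
  one tank load at density 1 kg/L, the contact fraction to 3×10⁻⁴, and the
  AI content is the mix concentration `applied AI mass / total mix mass`.
  Hands-only attenuation, as in M&L.

## Parameters and defaults

The three reference tables (formulation contact fractions by concentration
band; equipment deposition factors from 1000 ppm for a knapsack down to
0.001 ppm for a charcoal-filtered sealed cab; clothing protection factors
from 50% for underwear to 99% for a HazMat coverall) ship as versioned,
comment-headed CSVs so that a parameter update is a reviewable diff. Two
interpretive choices are baked into the packaged tables and documented in
their comment headers:

* Concentration bands are half-open on the left — [0,30), [30,60), [60,80),
  [80,100] percent — so the boundaries 30/60/80 deterministically belong to
  the upper band.
* The charcoal-filtered-cab deposition entry is the forced-ventilation value
  reduced by 99% (0.1 × 0.01 = 0.001 ppm), preserving the
  order-of-magnitude-per-step progression of the equipment ladder.

Everything the tables do not fix lives in `engine_settings()`:

| parameter | default | rationale |
|---|---|---|
| body region weights | head 0.06, face 0.04, hands 0.20, body 0.60, feet 0.10 | adult body-surface proportions; declared, not measured |
| MAN contact fraction | 3×10⁻⁴ | the dilute-liquid (<30% band) contact fraction — spray mix is always dilute |
| MAN handled mass | one tank load, 1 kg/L | the cleaned equipment holds about one tank of residue |
| tier thresholds | green < 50%, red > 100% | 100% of AOEL is the regulatory bound; 50% gives the borderline band a quantitative meaning |
| crop-height / pressure multipliers | 1.0 | both are real determinants, but no established effect sizes exist; defaults must not invent them |
| operator body weight | 60 kg | the EFSA operator-exposure convention |

Protection factors for item classes absent from the endorsed clothing table
(gloves, mask, headdress, footwear) are package defaults chosen consistently
with its generic-vs-technical span (generic gloves 0.90, specific gloves
0.99, headdress 0.90, mask 0.90 — as dermal face protection only, inhalation
is not modelled — shoes 0.70, boots 0.99). They are marked `default` in the
protection table's `source` column and flagged as such in every report's
audit appendix.

A single dermal absorption coefficient per active ingredient is applied to
all three phases; regulatory practice sometimes distinguishes concentrate
from dilute absorption, but the product database carries one value, so one
is used.

## Worked reference scenario

The packaged database's first entry is a worked exercise product: `KILLER`,
a 50% powder of the active ingredient `ACTIVOL`, GAP 100 g/ha, AOEL
0.05 mg/kg, dermal absorption 5%. Treating 10 ha at 10 hL/ha with a
1000 L tank from an open tractor, with no PPE at all and a 60 kg operator:

```{r worked}
tables <- load_reference_tables(default_tables_dir())
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
```

M&L dominates (1.25 of 2.25 mg absorbed) because the concentrate is
handled bare-handed — which is why the what-if search finds that gloves
alone turn the verdict green:

```{r whatif}
suggest_improvements(scenario, tables, max_changes = 1)
```

The search is exhaustive over the finite upgrade lattice (better PPE item
per region and phase, lower-deposition equipment; at most a few dozen moves,
so combinations up to `max_changes` remain desk-scale). It never touches
agronomic givens — product, area, AOEL — and every quoted risk is the result
of actually re-assessing the modified scenario.

## What the synthetic generator does and does not emulate

`generate_random_scenario()` drives the property and equivalence suites. It
samples areas in 0.1–100 ha, spray volumes in 1–20 hL/ha, tanks of
100–3000 L, pressures of 1–10 bar, any product, equipment and PPE
combination, and skips M&L with probability 0.1 — the breadth of conditions
a national user base would enter, uniformly and independently. It does
*not* emulate correlations of real farm practice (large areas co-occur with
closed tractors; knapsacks with small plots), label-compliant dose checks,
weather, or operator behaviour (glove re-donning, cab-interior
contamination — the latter two are surfaced as report warnings, not
quantified). Passing tests therefore demonstrate the arithmetic contract of
the model over its whole input domain, not field accuracy, which only a
measurement campaign can establish.

## Numerical choices

* Internal arithmetic is double precision throughout; reports round to 3
  significant figures for display, and the tier is always decided on the
  unrounded risk.
* The per-phase ledger stores `retained = potential − skin_loading`, so mass
  conservation holds exactly in the representable arithmetic.
* JSON reports serialize doubles at 17 significant digits, so a reparsed
  report is numerically identical to the in-memory result.
* Tier boundaries belong to yellow: risk exactly 50% or exactly 100% of
  AOEL is borderline, not safe and not yet a violation.
* `n_tank_loads` is `ceiling(spray volume / tank volume)`, floored at one;
  it is reported (an event-based M&L model would scale with it) but the
  implemented M&L model scales with handled mass, which is the conservative
  reading when loads are partial.
* Degenerate inputs fail fast at parse or load time with the offending key
  or cell named; `validate_scenario()` returns findings (error / warning /
  info) rather than throwing, so a UI can show all problems at once.

Test problem sizes: the equivalence suite compares the engine to an
independently coded closed-form expression on 200 seeded scenarios (to
1×10⁻⁹ relative); the property suite runs over a thousand randomized checks
of monotonicity, linearity, conservation and band totality; the what-if
soundness suite re-assesses every suggestion on 50 seeded red scenarios.

## Known limitations

The calculation chain is a reconstruction calibrated to published parameter
tables, not a validated field model: measured operator exposure is routinely
one to three orders of magnitude below the AOEL, so the defaults here are
deliberately conservative screening values. Inhalation is not modelled (the
mask's factor counts only as dermal face protection). The crop-height and
pressure determinants are plumbed through but neutral by default. The demo
product database is 16 entries, one real worked exercise plus 15 clearly
labelled synthetic records — it is a fixture for the machinery, not an
authorization registry.
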