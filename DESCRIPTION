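Package: pestrisk
Title: Preventive Occupational Risk Assessment for Agricultural Pesticide Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic, preventive risk assessment of operator exposure
    during agricultural pesticide treatments. From a declarative scenario
    (crop, treated area, product, formulation, spray equipment, per-phase
    personal protective equipment) the package computes phase-wise potential
    dermal exposure for mixing-and-loading, application and
    maintenance-and-cleaning, attenuates it by protection factors, converts
    skin loading to absorbed dose via the dermal absorption coefficient, and
    expresses the daily absorbed dose as a percentage of the Acceptable
    Operator Exposure Level (AOEL) with a three-tier (green/yellow/red)
    verdict. Ships versioned reference tables (formulation contact
    fractions, equipment deposition coefficients, clothing protection
    factors) and a demonstration active-ingredient database, a what-if
    search for minimal scenario improvements, report rendering to JSON and
    Markdown, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
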