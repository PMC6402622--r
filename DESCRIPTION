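Package: woundcea
Title: Cost-Effectiveness Analysis of Specialist Wound Care Clinics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-state Markov cohort model comparing specialist wound
    clinics with usual care for chronic wounds over a one-year horizon,
    with monthly cycles. Implements transition-probability conversion
    between time horizons, deterministic cost and QALY accrual under
    selectable cycle-accounting conventions, probabilistic sensitivity
    analysis with beta/gamma parameter distributions, the net-monetary-
    benefit decision framework with cost-effectiveness acceptability
    curves, declarative scenario analyses, and a synthetic patient-cohort
    generator with a matching parameter estimator so the whole pipeline
    is testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
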