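Package: fitreach
Title: Decision-Analytic Model of Mailed FIT Colorectal Cancer Screening Outreach
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic difference-equation cohort model of a five-year
    mailed fecal immunochemical test (FIT) colorectal cancer screening
    program for unscreened safety-net (FQHC) patients, with layered program
    costing (direct, indirect, start-up, payer colonoscopy costs), projection
    of screening and cancer outcomes, incremental and average
    cost-effectiveness analysis with strict and extended dominance, one-way
    and threshold sensitivity analysis, and a patient-level stochastic
    microsimulation used as a Monte Carlo cross-check of the deterministic
    engine. Nine scenarios (three outreach strategies crossed with three
    organizational configurations) are shipped as editable YAML
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
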