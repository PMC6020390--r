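Package: wfshear
Title: Longitudinal Audiometric Analysis for Wolfram Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for natural-history analysis of sensorineural hearing
    loss in Wolfram syndrome and similar rare-disease cohorts. Computes
    per-ear audiometric metrics (pure tone average, high frequency
    average, unaided Speech Intelligibility Index), classifies hearing
    status and ranks ears, summarises cohort symptom-onset tables, fits
    random-slope linear mixed models of audiometric progression, and
    sizes two-arm clinical trials by Monte Carlo simulation of the
    treatment-by-time interaction test. A synthetic-cohort generator
    produces longitudinal per-ear, per-frequency audiograms with 5-dB
    quantization, equipment ceilings, missed visits and conductive-loss
    sessions, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
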