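Package: hypostage
Title: Validation Toolkit for the Swiss Clinical Staging Model of Accidental Hypothermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well the four-stage Swiss clinical staging
    model of accidental hypothermia predicts measured core body temperature.
    Implements the rule-based stage assignment from consciousness (Glasgow Coma
    Scale or AVPU) and vital signs, stage-versus-temperature concordance tables
    with per-stage summary statistics (confidence and prediction intervals),
    adjacent-stage ROC analysis with Youden-index optimal temperature
    thresholds, hospital-versus-literature cohort comparison, and a seeded
    synthetic cohort generator based on moment-matched truncated normal
    temperature distributions, so the full pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
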