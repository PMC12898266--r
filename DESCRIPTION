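Package: longlabs
Title: Longitudinal Summaries of Clinical Measurements and Mortality Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes a patient's complete longitudinal record of vital signs
    and laboratory results into thirteen per-measurement parameters spanning
    seven clinical attributes (current control, chronicity, disease burden,
    refractoriness, tendency to relapse, lability and temporal trends), using
    time-weighted trapezoidal areas, abnormal-value cluster detection and an
    incremental running summary. Provides the downstream prediction pipeline:
    per-measurement subset logistic models, an attribute-set-wise stepwise main
    model with backward removal, patient-level predicted death probabilities,
    and AUROC estimation and comparison (DeLong) against age and
    comorbidity-score baselines. Includes a synthetic electronic-health-record
    cohort generator with irregular, abnormality-intensified visit times so the
    whole pipeline can be exercised end to end without clinical data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Rcpp,
    pROC,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
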