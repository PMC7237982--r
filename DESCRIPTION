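Package: ewsbench
Title: Benchmarking Points-Based Early Warning Scores on Ward Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven computation of five points-based early warning
    scores (NEWS, MEWS, Between the Flags, qSOFA, SIRS) over longitudinal
    non-ICU inpatient data, with imputation to normal and last value carried
    forward; Sepsis-3 suspected-infection flagging from culture/antibiotic
    order dyads; cohort construction with first time-at-risk intervals; and
    evaluation of discrimination (AUC with DeLong or bootstrap confidence
    intervals), screening efficiency curves, operating points and alerting
    workload, including a calibrated synthetic electronic-health-record
    cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
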