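Package: wearimpute
Title: Wear-Time Scaling and Imputation for Minute-Level Activity-Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for handling non-wear missingness in minute-resolution
    commercial activity-monitor data (steps, heart rate, energy expenditure).
    Implements an hour/day/14-day wear-time scaling algorithm with minimum-wear
    validity thresholds, comparator imputation strategies (cohort and individual
    mean imputation, bootstrap predictive-mean-matching multiple imputation,
    Kalman smoothing under a local-level structural model, and iterative random
    forest imputation), heart-rate-reserve intensity classification, simulators
    for non-wear gap insertion and for synthetic 14-day cohorts with circadian
    structure, and the evaluation statistics used to compare methods (RMSE,
    paired TOST equivalence tests, two-way agreement ICC, autocorrelation
    profiles).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
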