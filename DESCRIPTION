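Package: ventwatch
Title: Predicting Onset of Invasive Mechanical Ventilation from ICU Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting the onset of invasive mechanical
    ventilation (IMV) in hypoxemic intensive-care patients from irregularly
    sampled vitals and laboratory time series. Implements hourly
    triplet featurization (value, presence mask, time since last
    measurement), gap-horizon sliding-window sample enumeration,
    gradient-boosted-tree classification with imbalance weighting and
    random hyperparameter search, transfer-learning adaptation of a
    source-cohort model to a small target cohort by continued boosting,
    an evaluation battery (ROC/AUC, FPR-anchored confusion matrices,
    F-beta, Matthews correlation, precision by probability bin, repeated
    split confidence intervals), lagged correlation / DAG / tier feature
    analyses, and a seeded synthetic-ICU cohort generator with a
    configurable source-to-target domain shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
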