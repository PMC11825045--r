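Package: mpvent
Title: Mechanical Power of Ventilation and ICU Mortality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between the mechanical power
    of ventilation and intensive-care mortality. Computes ideal-body-weight
    normalised, time-weighted-average mechanical power from pressure-controlled
    ventilation time series, derives hypoxemia-stratified safe upper limits by
    a rank-test-gated survivor-percentile procedure, fits a suite of mortality
    prediction models with minority oversampling and cross-validation, and
    runs a closed-loop individualization algorithm that searches ventilator
    settings until the predicted outcome flips to survival. Includes a
    synthetic ICU cohort generator so the full pipeline is testable without
    access to restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    randomForest,
    xgboost,
    e1071,
    rpart,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
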