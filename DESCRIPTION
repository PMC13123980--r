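Package: heatrisk
Title: Conditional Heat Index Estimation and Scenario-Based Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the U.S. National Weather Service Heat Index from
    3-hourly dry-bulb temperature and relative humidity records using the
    two-stage Steadman/Rothfusz procedure with low- and high-humidity
    adjustments, classifies records into heat-health risk categories, and
    models the conditional dynamics of the Heat Index with leakage-safe
    lagged features. A registry of estimators (persistence baseline,
    ARIMAX/SARIMAX, random forest, gradient boosting) is fitted on a
    chronological split and evaluated with expanding-window time-series
    cross-validation, residual diagnostics, and scale-free accuracy metrics
    including the mean absolute scaled error against a persistence
    benchmark. Multi-year climatological scenarios (mean shifts plus
    seeded stochastic variability on monthly climatology) are projected
    recursively at 3-hour resolution, with empirical 95% prediction
    intervals from tree-level ensemble dispersion and coverage/width
    calibration. Includes a seeded synthetic generator for Dhaka-like
    3-hourly climate series for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    lmtest,
    car
Config/testthat/edition: 3
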