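Package: sepkin
Title: Kinematics Features from Hourly Vital Signs for Early Sepsis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms multivariate hourly vital-sign series (heart rate,
    oxygen saturation, temperature, systolic and diastolic blood pressure,
    respiration rate) into kinematics features: the unit relative-position
    vector and the scalar projections of velocity and acceleration of a
    patient relative to an estimated "sepsis position" in six-dimensional
    vital-sign space. Provides a preprocessing cascade for pipe-separated
    hourly ICU records (limit clipping, fixed-width windowing, cohort
    hourly-mean imputation, linear interpolation, trailing moving-average
    smoothing, max-normalisation, cohort balancing), a seeded
    synthetic-cohort simulator with planted ground truth, and a classifier
    comparison harness (LSTM, 1-D CNN, linear neural network, penalised
    logistic regression, decision tree) with stratified k-fold
    cross-validation, accuracy summaries and calibration curves, so the
    kinematics representation can be compared against raw vital signs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    glmnet,
    rpart,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
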