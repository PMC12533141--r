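Package: eefusion
Title: Personalized Dynamic-Static Feature Fusion for Energy Expenditure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction, modelling and
    interpretation for predicting energy expenditure (kcal/min) during
    incremental treadmill exercise from wrist-worn tri-axial acceleration,
    ECG-derived RR-interval telemetry and static physiological traits.
    Includes a synthetic-cohort generator for the incremental (RAMP-style)
    protocol, Local-Outlier-Factor cleaning with Kalman smoothing, a
    22-feature time/frequency-domain feature bank over 10-second windows,
    an autoregressive baseline plus LSTM and CNN+LSTM dynamic-static fusion
    regressors trained with Adam, leave-one-subject-out cross-validation
    with Bland-Altman agreement analysis, and Shapley-value attribution
    (expected gradients) with intensity-stratified contribution curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
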