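Package: pefrisk
Title: Individualized Asthma Risk Prediction from Indoor Air Quality and
    Peak-Flow Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for individualized short-term asthma risk prediction from
    indoor air-quality sensor streams and twice-daily peak expiratory flow
    rate (PEFR) diaries. Converts minute-cadence PM2.5, CO2, temperature and
    humidity records plus a 30-minute activity diary into daily inhalation-
    weighted exposure features, derives a patient-specific critical PEFR
    value from the patient's own historical flow distribution, classifies
    next-day high-risk days with a transfer-learning-augmented logistic
    regression (a population-pooled neural network fine-tuned per patient
    whose last-hidden-layer activations feed a logistic head, with SMOTE
    oversampling for the rare risk class), estimates conditional PEFR
    quantiles with linear quantile regression refit under a variable
    sliding-window protocol, and combines both models in a daily decision
    engine that issues alerts on predicted drops of the critical quantile.
    Includes a calibrated synthetic cohort generator so the full pipeline is
    exercisable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
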