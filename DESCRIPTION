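Package: adrnet
Title: Antidepressant Response Prediction from Longitudinal Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts a depressed patient's next-visit Hamilton Depression
    Rating (HAM-D) score from tabular clinical covariates and the prescribed
    antidepressant combination, using a shallow neural network with a patient
    representation layer, an additive drug-embedding layer for prescriptions,
    and a linear regression head trained by Adam on mean squared error.
    Includes the surrounding pipeline: a synthetic longitudinal cohort
    simulator, random-donor imputation, missingness filtering and a nested
    cross-validated elastic-net feature-selection protocol, regression and
    remission-classification evaluation via an autoregressive score rollout,
    exhaustive prescription ranking, and patient-similarity retrieval from
    learned representation vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    randomForest,
    xgboost,
    nnet,
    caret,
    yaml,
    optparse
Config/testthat/edition: 3
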