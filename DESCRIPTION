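Package: arrestcast
Title: Event-Anchored Time-Series Features for Cardiac-Arrest Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds clinical prediction models from event-anchored vital-sign
    time series, instantiated for cardiac-arrest prediction in a pediatric
    intensive care unit. Provides a synthetic cohort simulator for progressive
    shock trajectories, two-resolution event-anchored windowing with
    carry-forward imputation, clinically derived latent variables (pulse
    pressure, mean arterial pressure, shock index, oxygen-delivery index),
    per-window trend features (slope, intercept, mean, slope/mean and
    between-window mean ratios), five-way feature-subset construction,
    recursive feature elimination and SVM-weight feature selection, and
    holdout validation of linear, tree, neural-network and support-vector
    classifiers with accuracy, sensitivity, specificity and AUROC reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    e1071,
    rpart,
    nnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
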