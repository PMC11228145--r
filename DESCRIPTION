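Package: glucotab
Title: Group-Informed Attentive Tabular Networks for Blood Glucose Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts diabetes-mellitus progression (fasting blood glucose) from
    routine clinical and physical-examination indicators. Implements a
    cluster-informed multi-stage missing-data imputation scheme (DBSCAN patient
    grouping, cluster-level mean features, stepwise gradient-boosted
    prediction), dual-layer data augmentation (bounded additive perturbation of
    sample copies and appended group-level mean features), and a sequential
    attentive tabular network whose sparsemax attention operates over mask
    units, so that all indicators of one clinical panel share a single
    attention value. Per-step and aggregate feature-importance masks expose
    which panels drive each prediction. Includes a synthetic-data generator
    emulating the grouped-panel missingness structure of examination cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
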