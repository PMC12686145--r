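Package: cafsig
Title: CAF-Signature Scoring, Ensemble Model Search and Spatial Proximity
    Analysis for Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating cancer-associated fibroblast
    (CAF) gene-signature predictors of immune-checkpoint-inhibitor response.
    Provides single-sample rank-weighted running-sum gene-set scoring and the
    up-minus-down Caf.Sig score, an ensemble feature-selection by classifier
    model-search framework with leave-one-out cross-validation and
    cross-cohort AUC ranking, per-gene odds-ratio meta-analysis, spatial
    cell-type proximity analysis via k-nearest-neighbour distances with
    robust rank aggregation, an evaluation battery (ROC, confusion matrix,
    calibration, decision curves, logistic comparison), and synthetic
    multi-cohort and tissue-section generators with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    glmnet,
    randomForest,
    xgboost,
    e1071,
    metafor,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
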