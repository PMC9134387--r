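Package: snapqsar
Title: Multi-Angle 3D Snapshot Rendering and Image-Probability Feature
    Fusion for QSAR Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a combination QSAR workflow in which each compound's
    3D conformer is rendered as a set of ball-and-stick snapshot images
    taken at fixed rotation-angle increments, a binary image classifier is
    trained on the snapshots, and the per-compound median prediction
    probability is appended to a molecular-descriptor table as an extra
    feature for regression. Includes stratified nested dataset splitting
    (five folds, five train/test patterns, classifier train/validation
    split, regression hold-out and cross-validation), an algorithm
    competition selected by lowest cross-validated RMSE, normalized
    permutation feature importance averaged over patterns, evaluation
    metrics (RMSE, R-squared, rank-based AUC), a PCA chemical-space check,
    and a reproducible synthetic compound-library generator for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: OpenBabel (via ChemmineOB); Python (>= 3.8) with
    RDKit on the PATH for conformer embedding
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    png,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
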