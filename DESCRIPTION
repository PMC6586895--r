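Package: synergyScreen
Title: Prediction of Drug-Combination Synergy from Multi-Omics Screen Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature engineering and machine-learning prediction of
    Loewe-excess synergy scores in large drug-combination screens.
    Builds combination-level features from chemical structure (MACCS keys),
    putative targets and their protein domains and pathways, monotherapy
    dose-response parameters, link-prediction indices on a drug synergy
    network (common neighbors, Jaccard, Adamic-Adar), co-expression module
    summaries of cell-line transcriptomes, and filtered mutation and
    copy-number features. Trains five regression backends (linear, lasso,
    SVM, random forest, gradient boosting), evaluates them with the
    weighted average Pearson correlation over drug combinations under
    repeated 10-fold cross-validation, and interprets fitted boosters via
    gain-based feature-group importance and Kolmogorov-Smirnov
    target-association tests. Includes a synthetic screen generator with
    planted co-expression modules, copy-number/expression coupling and a
    recoverable synergy-generating model, so the full pipeline is testable
    without access-controlled screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    xgboost,
    glmnet,
    e1071,
    ranger,
    jsonlite
Suggests:
    ChemmineOB,
    mclust,
    pROC,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
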