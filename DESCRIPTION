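Package: skinsens
Title: Human Skin Sensitization QSAR Modeling from Patch-Test Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curation, featurization, modeling and interpretation pipeline
    for predicting human skin sensitization hazard and potency from
    patch-test derived compound tables. Provides chemical structure
    standardization and biological deduplication, fingerprint and
    physicochemical descriptor featurization, random forest, gradient
    boosting and support vector machine classifiers with Bayesian
    hyperparameter search and stratified five-fold external
    cross-validation, threshold-moving calibration by geometric-mean
    maximization, a Euclidean nearest-neighbor applicability domain,
    additive per-feature attributions with atom-level fragment
    contribution maps, activity-landscape roughness (ROGI) analysis and
    chemical-space grouping, plus a seeded synthetic structural-alert
    data generator for fully offline testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    xgboost,
    e1071,
    lhs,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC,
    optparse
SystemRequirements: Python (>= 3.8) with rdkit and umap-learn on PATH as
    'python' (used by the bundled chemistry backend).
Config/testthat/edition: 3
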