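Package: offpanel
Title: Imbalance-Aware Off-Target Safety Panel Classifiers from Sparse
    Inhibition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-target binary activity classifiers for small-molecule
    off-target safety panels from sparse compound-by-target percent-inhibition
    or binary-activity tables. Curates tabulated panel data (canonical SMILES,
    duplicate handling), computes 1024-bit ECFP4 fingerprints and physchem
    descriptors through an RDKit backend, produces stratified
    train/validation/test splits, trains per-target feed-forward neural
    networks (grid-sampled hyperparameter search, balanced-accuracy
    checkpointing, early stopping) alongside a Random Forest baseline, and
    evaluates everything with an imbalance-aware metric suite (balanced
    accuracy, MCC, F1, AUC, AUCPR). New structures can be scored against a
    trained panel with a bounding-box applicability-domain flag, and PCA
    chemical-space overlap diagnostics support dataset-combination studies.
    A synthetic panel generator with planted substructure activity rules makes
    the whole workflow testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    readxl,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the
    PATH (configurable via option 'offpanel.python').
Config/testthat/edition: 3
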