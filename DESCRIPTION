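Package: coaxStackR
Title: Coaxial Stacking Prediction for RNA Multi-Way Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts coaxial helical stacking configurations in RNA
    multi-way junctions from sequence and dot-bracket secondary structure.
    Junctions of any order are decomposed into pseudo two-way stem pairs,
    each pair is scored by a random-forest classifier over twelve
    sequence, topology and Turner nearest-neighbor thermodynamic features,
    and the junction-level configuration is reconstructed by maximum-weight
    matching on a cycle graph. Includes a synthetic junction generator with
    a planted stacking rule, dataset curation utilities (dot-bracket
    Needleman-Wunsch redundancy filtering, stratified splitting), KDE-based
    decision thresholding, Gaussian-process hyperparameter search, and
    evaluation metrics (exact configuration accuracy, pairwise accuracy,
    binary classification metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger,
    rpart,
    pROC,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'coaxStackR-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'classifier.R'
    'bayesopt.R'
    'dotbracket.R'
    'curation.R'
    'evaluation.R'
    'features.R'
    'reconstruction.R'
    'synthetic.R'
    'thermo.R'
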