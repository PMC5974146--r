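Package: plantmito
Title: Plant Mitochondrial Protein Prediction from Sequence, Profile and
    Co-Expression Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a plant protein is targeted to the
    mitochondrion, including proteins that lack a cleavable N-terminal
    pre-sequence. Builds four feature blocks per protein (N-terminal
    amino-acid frequencies, N-terminal and global position-specific
    scoring matrix features, and gene co-expression k-nearest-neighbour
    scores from meta-analytically combined Pearson correlations across
    expression datasets), trains either a radial-basis support vector
    machine or an ensemble of maxout/dropout feed-forward networks under
    stratified cross-validation, and converts raw classifier scores into
    specificity-calibrated calls using a held-out negative reference set.
    Ships a synthetic-data generator emulating the assumed signal
    structure, a full evaluation toolkit (confusion metrics, MCC,
    trapezoidal ROC/PR AUC, bootstrap AUC comparison), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
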