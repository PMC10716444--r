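Package: stackac4c
Title: Stacked Ensemble Prediction of N4-Acetylcytidine (ac4C) Sites in mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of N4-acetylcytidine (ac4C) sites in
    mRNA from fixed-length nucleotide windows. Implements three feature
    encoders (k-mer composition, pseudo K-tuple nucleotide composition with
    dinucleotide physicochemical correlations, and electron-ion interaction
    pseudopotential trinucleotide features), cluster-centroid undersampling
    for imbalanced benchmarks, and a two-layer stacking ensemble in which
    five base classifiers feed out-of-fold probabilities to an L2-regularized
    logistic meta-learner. Includes a full imbalance-aware evaluation suite
    (sensitivity, specificity, accuracy, Matthews correlation, ROC and
    precision-recall areas), stratified cross-validation, a seeded synthetic
    benchmark generator, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    nnet,
    pROC,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
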