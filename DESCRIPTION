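Package: tcrlearn
Title: Deep Representation Learning for T-Cell Receptor Repertoires
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint featurization of T-cell receptors from CDR3 amino-acid
    sequences and V/D/J gene usage via trainable embeddings and a
    convolutional stack; an unsupervised variational autoencoder producing
    continuous latent TCR representations; supervised per-sequence
    classification and regression with Monte-Carlo cross-validation; a
    weakly supervised multi-instance repertoire classifier with an adaptive
    inverse-square-root-unit (AISRU) attention mechanism and
    concept-proportion pooling; TCR distance metrics (latent Euclidean,
    Hamming, k-mer, global-alignment) with clustering and K-nearest-neighbor
    benchmarking; and model interpretation tools including learned-motif
    extraction, residue-sensitivity profiles and Residue Sensitivity Logos.
    Includes a seeded generator of synthetic motif-implanted repertoires so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
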