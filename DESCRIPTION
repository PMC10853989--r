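Package: radlatent
Title: Autoencoder Latent-Space Compression and Staged Classification of
    Brain-Tumor Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for three-class malignant brain-tumor
    classification (glioblastoma, primary CNS lymphoma, parenchymal
    metastasis) from MRI-derived radiomic feature tables. Per-ROI-mask
    autoencoders compress the high-dimensional radiomic space to a small
    latent representation selected by a reconstruction-error grid search;
    classification uses a multilayer perceptron, either directly on the
    three classes or as a two-stage multiclass-decomposition cascade with
    minority-class upsampling. Includes a seeded synthetic-cohort generator
    with low-rank class structure and block missingness, leakage-safe
    preprocessing (z-score standardization and imputation fitted on training
    folds only), repeated stratified cross-validation, and one-vs-rest /
    micro-averaged evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
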