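Package: grvsnn
Title: Gated Residual Variable Selection Networks for Multi-Task Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-task genome-wide phenotype prediction with gated residual
    variable selection neural networks. Fuses reduced-rank loadings of the
    pedigree-based additive relationship matrix with SNP marker dosages into a
    joint tabular input, trains per-feature gated residual blocks with a global
    softmax variable-selection layer and a multi-trait output head, and
    evaluates predictions with mean squared error, Pearson correlation and
    distance correlation under repeated stratified cross-validation. Includes
    a pedigree/genotype/phenotype simulator, hyperparameter search via a
    tree-structured Parzen estimator, readers for dosage tables and pedigrees,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
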