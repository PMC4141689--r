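Package: memlgwas
Title: Multi-SNP Genome-Wide Association by EM Bayesian Lasso with a
    Pedigree Polygenic Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiple-SNP genome-wide association analysis of
    continuous traits in pedigreed populations. Implements MEML, an
    expectation-maximisation algorithm for joint maximum-a-posteriori
    shrinkage estimation of many SNP effects under a hierarchical
    double-exponential (Bayesian Lasso) prior, with a residual polygenic
    effect distributed according to the pedigree additive relationship
    matrix and treated as missing data. Also provides the single-marker
    mixed-model association scan (SMMA) used as a genome-wide prescreen,
    permutation-based genome-wide significance thresholds, SNP and
    individual quality control for PLINK-style text genotype files,
    pedigree relationship-matrix construction by the tabular method, and
    a gene-dropping simulator for power and false-positive-rate studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
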