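Package: pharaohgee
Title: Pathway Analysis of Rare Variants for Clustered Phenotypes via
    Penalized Generalized Estimating Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway-level association testing of rare variants against
    clustered (repeated or multivariate) phenotypes. Gene burdens are
    collapsed from rare-variant dosages, combined into latent pathway
    components through a hierarchical structured-component model, and
    linked to the phenotypes by generalized estimating equations with
    separate ridge penalties on the gene-to-pathway weights and the
    pathway-to-phenotype coefficients. Includes k-fold cross-validation
    of the penalty pair by predictive quasi-deviance, permutation-based
    Wald-type pathway and gene tests with Benjamini-Hochberg and
    Westfall-Young corrections, a simulator of rare-variant pathway data
    with liability-threshold binary phenotypes, and a power/type-I-error
    study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
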