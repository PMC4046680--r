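Package: scpca
Title: Supervised Categorical Principal Component Analysis for SNP-Set
    Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene- and pathway-based aggregated association analysis of
    case-control SNP genotype data. Genotypes coded 0/1/2 are treated as
    three unordered categories and summarized by a multinomial
    exponential-family principal component analysis (categorical PCA)
    fitted by alternating damped Newton updates with QR
    re-orthonormalization. The first principal component of a
    supervised, significance-screened SNP subset is tested against the
    phenotype by logistic regression; set-level significance comes from
    a permutation null of the maximal subset statistic with
    Benjamini-Hochberg adjustment across sets. Standard PCA and
    logistic (Bernoulli) PCA score extractors are included as
    comparison arms, together with an LD-block case-control genotype
    simulator with penetrance-based disease models and power/ROC
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
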