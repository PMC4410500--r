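Package: vclrt
Title: Permutation-Based Variance Component Likelihood Ratio Tests for
    SNP-Set Association in Logistic Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based (multilocus) association testing for binary
    case-control phenotypes under a logistic mixed-effects model in which
    the K SNP effects of a gene share one variance component.  Fits the
    model by penalized quasi-likelihood (PQL), forms the likelihood ratio
    statistic from the quasi log-likelihood of the PQL working response,
    and obtains its null distribution by a permutation (or parametric
    bootstrap) procedure.  Ships the classical comparators: chi-square
    mixture reference distributions for the boundary null and the
    score-based variance component (SKAT-style) test with an
    eigenvalue-mixture tail probability.  Includes generators for
    correlated-genotype simulation studies and Monte-Carlo type-I-error
    and power experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
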