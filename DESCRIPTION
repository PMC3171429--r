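Package: mvbench
Title: Model-Based Benchmarking of Missing-Value Imputation for Microarray Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-class log-ratio gene-expression data with
    block-correlated gene effects and heteroscedastic noise, generates
    missing values either at random or where measurement noise is largest
    (quality-based masking), and benchmarks six imputation algorithms
    (row average, K-nearest-neighbour, local least squares with Euclidean
    or correlation candidate selection, least-squares regression
    imputation, and Bayesian principal component analysis) by their effect
    on downstream classification. Feature selection uses a two-sample
    t-statistic filter and sequential forward floating search driven by
    bolstered resubstitution error; classifiers are linear discriminant
    analysis, 3-nearest-neighbour and a linear support vector machine.
    Test samples are completed one at a time using only the training data,
    so imputation is part of the classification rule, and imputation
    accuracy is scored by root-mean-square error normalised against the
    noise-free true signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    class,
    e1071,
    generics,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
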