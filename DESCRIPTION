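Package: forestscreen
Title: Forest-Based Feature Screening for Ultrahigh-Dimensional Continuous Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Feature screening for ultrahigh-dimensional continuous
    phenotypes, aimed at genome-scale predictor sets where complex
    (interactive, nonlinear, correlative) genetic architectures defeat
    marginal association measures.  Ranks features by six measures: sure
    independence screening (SIS) and its iterative variant (ISIS),
    conditional correlation screening given a covariate (CC-SIS, ICC-SIS),
    distance correlation screening (DC-SIS), and out-of-bag permutation
    variable importance from a regression random forest (RF-PVIM), which
    captures epistasis-like effects that marginal measures miss.  Includes
    a four-design simulation benchmark with AR(1)-correlated Gaussian
    features, screening performance criteria (average causal-feature
    ranks, minimum model size and its quantiles, selection power within a
    candidate budget), and readers for delimited genotype/phenotype data
    with a Manhattan-style importance table keyed to genomic position.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
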