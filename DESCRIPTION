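Package: landaufit
Title: Detecting Continuous Transitions to Bistability in Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of a continuous (supercritical pitchfork)
    transition to bistability from cross-sectional gene expression data.
    Fits a quartic-exponential "Landau" distribution along the dominant
    variance axis (first principal component), selects between the unimodal
    Gaussian, Landau, and two-component Gaussian-mixture models by the
    Bayesian Information Criterion, ranks genes by the fraction of their
    variance aligned with the bistable axis, and computes per-gene marginal
    densities of the fitted model. Includes a stochastic gene-regulatory
    network simulator (Euler-Maruyama integration of saturating all-to-all
    dynamics) with a mean-field critical point, used for power analysis and
    as a fully synthetic data generator. Designed for the
    high-dimension-low-sample-size regime common in transcriptomics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
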