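Package: ewsbench
Title: Benchmarking Multivariate Early-Warning Indicators of Resilience Loss
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation benchmark for multivariate early-warning indicators of
    critical transitions. Provides a stochastic bipartite plant-pollinator
    (facilitation-competition) model driven slowly toward a zero-eigenvalue
    bifurcation, an Euler-Maruyama simulator with data-degradation transforms
    (shortened series, coarse sampling, measurement noise, multiplicative
    noise, variable subsets), thirteen multivariate resilience indicators
    (variance-, autocorrelation-, PCA-, MAF- and mutual-information-based),
    and an evaluation stage that scores each indicator as a clipped Kendall
    tau trend along the bifurcation sweep, including null-sweep specificity
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
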