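Package: hbmort
Title: Hierarchical Bayesian Smoothing of Sparse Stratified Mortality Rates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sparse stratified mortality data from
    linked census-mortality cohorts: linkage-bias weighting of death counts,
    a hierarchical Bayesian Poisson log-rate model with a linear age spline
    and shrinkage of stratum effects toward the covariate structure (fitted
    by MCMC via JAGS), draw-wise direct standardisation of posterior rates
    to a shared standard population, and rate-ratio summaries with credible
    intervals and a tail-probability significance rule.  Includes a
    synthetic linked-cohort generator emulating the structure of the
    confidential source data, and statistical disclosure-control utilities
    (random rounding to base 3 with a minimum publishable cell).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
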