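Package: ivbin
Title: Simulation-Based Comparison of Instrumental-Variable Estimators for
    Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for comparing instrumental-variable (IV)
    estimators of the causal effect of a continuous exposure on a binary
    outcome, in the many-weak-instruments setting typical of Mendelian
    randomization.  Provides a data-generating mechanism with hundreds of
    binomial instruments and copula-coupled unmeasured confounders
    (Gaussian, t, Clayton, Gumbel, and heavy-tailed-margin families with
    Kendall-tau calibration), six estimator families (two-stage least
    squares, two-stage predictor substitution and residual inclusion with
    probit and log links, limited-information maximum likelihood on the
    joint exposure-outcome likelihood, and split-sample inverse-variance
    weighted estimators), G-formula standardization to causal risk ratios
    and differences, and a scenario runner that summarizes estimates as
    mean and empirical standard error across iterations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    parallel,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
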