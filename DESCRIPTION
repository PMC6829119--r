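Package: flamix
Title: Fast Laplace Whole-Genome Regression and Iterative Single-Stage
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@flamix.dev",
           role = c("aut", "cre"))
Description: Non-MCMC, hyperparameter-free whole-genome regression with a
    per-marker Laplace prior fitted by coordinate descent (the fast Laplace
    model), together with an iterative single-stage solver that embeds the
    marker regression inside a mixed model for replicated, unbalanced
    multi-environment trial data (Laplace or Gaussian prior on marker
    effects). Includes forward-in-time breeding-population and trial
    simulators, a GBLUP oracle with EMMA-style REML, a simplified two-stage
    baseline, and cross-validation utilities for assessing predictive
    ability of breeding values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
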