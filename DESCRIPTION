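Package: numerbias
Title: Reciprocal Interference Between Numerosity and Mean Item Size in
    Visual Comparison Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing two-alternative
    forced-choice experiments in which observers compare either the
    numerosity or the mean item size of heterogeneous dot arrays.  The
    package builds geometry-valid dot-array stimuli under separation,
    containment and density constraints, enumerates balanced factorial
    trial designs, simulates binary choices from a parametric synthetic
    observer with log-Gaussian internal noise and an additive interference
    weight from the unattended dimension, fits cumulative-Gaussian
    psychometric functions by grid-based Bayesian inference (point of
    subjective equality, just-noticeable difference, Weber fraction,
    lapse), quantifies congruency effects and signed/unsigned interference
    biases with credible intervals obtained by convolving posterior
    marginals, tests bias distributions for bimodality with Hartigan's dip
    statistic and a Monte-Carlo uniform null, and links interference
    measures to external covariates through inverse-efficiency scores and
    (partial) correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
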