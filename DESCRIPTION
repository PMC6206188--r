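Package: openscr
Title: Open-Population Spatial Capture-Recapture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian estimation for open-population spatial
    capture-recapture (SCR) models of the Jolly-Seber type. Provides a
    simulator of multi-year camera-trap detection data under three
    activity-center movement models (constant, independent, Markovian
    Gaussian random walk truncated to the state space), a compiled
    Metropolis-within-Gibbs sampler with data augmentation for survival,
    recruitment, detection and density, a conditional-on-first-capture
    (Cormack-Jolly-Seber) variant, and a factorial simulation-study driver
    for assessing sensitivity of survival and density estimates to the
    state-space buffer and the movement specification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
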