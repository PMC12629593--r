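Package: firesync
Title: Emergent Collective Periodicity from Aperiodic Flashers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a group of intrinsically aperiodic
    flashers (such as Photinus carolinus fireflies) develops a common,
    well-defined collective rhythm. Implements the extreme-value
    ("first to flash") theory of the group interburst-interval
    distribution for any individual waiting-time density, including its
    moments, variance and mode behaviour; the histogram-spline envelope
    protocol for turning observed interburst intervals into a gridded
    density; a stochastic pulse-coupled integrate-and-fire swarm
    simulator with tunable coupling strength; burst detection and
    interval analysis for flash-event series; and Kolmogorov-Smirnov
    parameter sweeps to fit the coupling strength against reference
    interval distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
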