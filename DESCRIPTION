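Package: madm1
Title: Multi-Population ADM1 for Ammonia-Inhibited VFA-Fed Anaerobic Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extension of the Anaerobic Digestion Model No. 1 (ADM1) in
    which acetoclastic methanogenesis and syntrophic propionate oxidation are
    each carried by two competing populations with different half-saturation
    constants and free-ammonia inhibition constants. The package simulates a
    volatile-fatty-acid fed continuous stirred tank reactor through an ammonia
    step disturbance, computes per-acid degradation efficiencies from one-day
    mass balances, estimates the population-specific parameters by sequential
    bounded least squares, and generates synthetic observation sets (noisy VFA
    concentrations and community relative abundances) for recovery studies.
    The reaction system carries closed chemical oxygen demand, carbon and
    nitrogen balances, an algebraic acid-base/pH subsystem and headspace gas
    transfer with overpressure-driven outflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
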