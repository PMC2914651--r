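Package: sgdkinetics
Title: Rate-Parameter Inference for Stochastic Kinetic Models by
    Stochastic Gradient Descent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of kinetic rate constants for
    stochastic (Markov jump process) models of biochemical reaction networks
    from discrete time-course observations. Latent reaction paths between
    observations are sampled by reversible-jump Markov chain Monte Carlo,
    with jump proposals built automatically from the elementary modes of the
    stoichiometry restricted to the observed species; sampled paths yield
    Monte-Carlo estimates of the likelihood gradient, which drives an
    adaptive stochastic gradient ascent to the maximum-likelihood estimate.
    Both fully and partially observed systems are supported, along with exact
    Gillespie simulation, integer-programming construction of initial paths,
    truncated chemical-master-equation oracles for validation, and
    ready-made birth-death and auto-regulatory gene-network benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
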