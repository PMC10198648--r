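Package: ssesim
Title: Simulation and Sampling-Fraction Robustness Analysis for Hidden-State
    Diversification Models
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates phylogenies under joint evolution of an examined and a
    concealed trait with state-dependent speciation and extinction (SSE),
    degrades them by random or taxonomically biased tip sampling, fits
    hidden-state SSE models (examined-trait-dependent, concealed-trait-
    dependent, constant-rate, and combined parameterizations) by maximum
    likelihood with per-state sampling fractions, and summarizes
    model-selection error rates and parameter-estimation accuracy under
    correct and mis-specified sampling fractions. Includes a reduced
    two-state Bayesian arm with a uniform prior on the sampling fraction,
    adaptive MCMC and stepping-stone marginal likelihoods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
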