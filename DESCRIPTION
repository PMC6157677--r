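Package: clutchsim
Title: Individual-Based Simulation of Clutch-Size Evolution in Finite
    Breeding Seasons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discrete-time, energy-budget, individual-based simulator of
    repeated breeding attempts within a breeding season of finite length,
    under stochastic nest failure drawn from a beta distribution. Breeders
    alternate between foraging (energy recovery) and breeding (energy
    investment); a clutch of size c can only be started once reserves cover
    its full cost, so large clutches trade fewer, longer attempts against
    the multitasking strategy of many small ones. The package provides the
    season simulator with full energy accounting (including the "excessive
    reserve" of time and energy wasted at the end of the season), a
    closed-form renewal-style approximation of the expected wasted time on
    the lattice of possible attempt start times, replicate and
    parameter-sweep engines with season-length-standardized summaries,
    presets for the standard experiment designs (season length, hazard mean
    and variance, clutch-size-dependent predation, food availability), and
    a simulation-versus-analytic comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
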