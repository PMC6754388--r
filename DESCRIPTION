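Package: oxymat
Title: Oxygen Reaction-Transport Modelling and Flux Budgets for Subaerial
    Microbial Mats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying oxygen cycling in subaerial photosynthetic
    microbial mats. Implements an explicit one-dimensional finite-difference
    (FTCS) oxygen reaction-transport model with Michaelis-Menten
    photosynthesis-irradiance and respiration kinetics, Fick's-law flux
    estimation and second-derivative net-rate inversion from microsensor
    depth profiles, an oxygen-equivalent flux-balance box model (organic
    matter accretion, methane efflux, 4-electron normalization), global
    areal-flux extrapolation calculators for land-coverage scenarios, and
    seeded synthetic-data generators emulating field microprofiles, organic
    carbon profiles, and cell-count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    deSolve
Config/testthat/edition: 3
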