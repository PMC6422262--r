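Package: spomscape
Title: Stochastic Patch Occupancy Metapopulations of Virtual Species on
    Mountain Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the range dynamics and fates of virtual mountain species
    under climate warming with a spatially explicit stochastic patch occupancy
    model (SPOM) on elevation grids. Provides synthetic landscape generators
    (pyramid, cone-in-a-square, roof, and Optimal Channel Networks obtained by
    metaheuristic minimization of total energy dissipation), digital elevation
    model import with rescaling and reporting masks, hypsographic curves,
    Gaussian elevational fitness with an equal-viability calibration based on
    the metapopulation capacity (leading eigenvalue of the landscape matrix),
    exponential-kernel colonization and fitness-dependent extinction dynamics,
    and a five-step warming experiment that classifies species fates
    (survivors, extinction debt, extinct suited/unsuited) over replicate
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
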