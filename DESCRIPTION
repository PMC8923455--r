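Package: alleesim
Title: Autocrine Signalling and Allee Effects in Cell Populations
Version: 0.1.0
Authors@R: person("alleesim", "maintainers", email = "alleesim@example.org",
    role = c("aut", "cre"))
Description: Hybrid individual-based simulation of cell populations whose
    division rate is boosted by a self-secreted, diffusible growth factor,
    together with its mean-field ordinary differential equation reduction,
    weak/strong Allee-effect classification, growth-curve fitting with
    AIC-based model selection against a nested logistic model, and
    mean-squared-displacement estimation of cellular diffusion from tracks.
    Includes generators for synthetic growth curves, Brownian track sets and
    lattice fixtures with known ground truth, plus a command-line interface
    for the end-to-end workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
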