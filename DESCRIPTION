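Package: cropnp
Title: Nitrogen-Aware Crop Growth Modelling for Controlled-Environment
    Agriculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic crop biomass simulation for controlled-environment
    (including bioregenerative life-support) agriculture.  Implements the
    modified energy cascade (MEC) areal biomass model for nine reference
    crops, a nitrogen-productivity (NP) growth model with logistic plant
    nitrogen dynamics and a nitrogen-use-efficiency decomposition, a hybrid
    simulator in which either model acts as the instantaneous limiting
    factor, empirical estimators of nitrogen productivity, nitrogen use
    efficiency and relative nitrogen accumulation rate from destructive
    harvest data with first-order error propagation, seeded least-squares
    parameter estimation by differential evolution with quasi-Newton
    polishing, moment-independent (Borgonovo) global sensitivity analysis
    with a classifier-screened sampling accelerator, and a synthetic
    hydroponic-experiment generator mirroring a multi-condition lettuce
    nitrogen study.  A command-line interface exposes every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
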