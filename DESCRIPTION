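Package: cicrsim
Title: Multiscale Stochastic Simulation of Calcium-Induced Calcium Release
    in Cardiac Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates excitation-contraction coupling in ventricular
    cardiomyocytes across scales: quasistatic Green-function solutions of
    dyadic-cleft calcium profiles with self-consistent single-channel
    currents, stochastic Markov gating of every ryanodine receptor (RyR)
    and L-type calcium channel (LCC), per-release-unit junctional-SR
    depletion and refill, a three-dimensional bidomain reaction-diffusion
    model for cytosolic and sarcoplasmic-reticulum calcium and buffers,
    and a rabbit ventricular action-potential model, coupled by a hybrid
    deterministic/stochastic adaptive time-stepping scheme with
    conductance-event batching. Includes pacing and restitution
    protocols, fluorescence-indicator readout, and excitation-contraction
    coupling gain analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    generics,
    ggplot2,
    rlang,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
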