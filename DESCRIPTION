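Package: thetafit
Title: Differentiable Population-Rate Modelling of Hippocampal Interneuron
    Theta-Phase Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates networks of hippocampal CA1 interneuron populations with
    the conductance-based refractory density (CBRD) method for leaky
    integrate-and-fire neurons and Tsodyks-Markram short-term synaptic
    plasticity, and fits all synaptic and current parameters by Adam gradient
    descent so that simulated population firing rates match von Mises
    theta-phase target profiles. Gradients are computed by a hand-derived
    reverse-mode adjoint of the numerical scheme. An independent Monte Carlo
    spiking simulator of the same network validates the population solver.
    Includes circular statistics, conductance decomposition, excitation to
    inhibition ratio analysis, and theta-frequency generalization sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
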