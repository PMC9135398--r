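Package: capclamp
Title: Capacitance Clamp Simulation and Electrophysiological Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate the capacitance clamp, a dynamic-clamp feedback
    protocol that makes an excitable cell behave as if its membrane capacitance
    were different. Provides conductance-based and passive cell models (RC
    circuit, two-compartment circuit, Wang-Buzsaki interneuron, ball-and-stick
    cable) with fast compiled integrators, the discrete-time clamp controller,
    capacitance estimation from charging curves (multi-exponential fits with
    F-test model selection and the mapping onto a two-compartment circuit),
    and an analysis suite for spike shape features, f-I curves, charge and
    energy metrics, temporal integration, and the impedance of a clamped RC
    circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
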