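Package: axondelay
Title: History-Dependence of Spike Conduction Delay in an Unmyelinated Axon Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Conductance-based multicompartment cable model of an unmyelinated
    crustacean motor axon with an electrogenic Na+/K+ pump, and the stimulation
    protocols and analyses characterizing the history-dependence of spike
    conduction delay: slow pump-mediated delay growth, fast non-monotonic
    dependence on instantaneous frequency, recovery-cycle (paired-pulse)
    prediction, closed-form conduction-velocity estimates, empirical delay
    regressions on sodium gating rates or spike trough/peak voltages,
    parameter-sensitivity analysis, and a surrogate spike-feature generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
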