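Package: pulsegate
Title: Pulse-Gated Entrainment in Multi-Rhythm Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of rhythm interaction in a small
    conductance-based (Hodgkin-Huxley type) cortical network producing a
    beta1 rhythm, together with its reductions down to a discrete
    pulse-gating model with analytic entrainment guarantees. Provides
    pulsatile drive generators, a compiled fixed-step network integrator,
    a leaky integrate-and-fire reduction, the abstract two-input gating
    model with transient and frequency-range bounds, and the event-time
    analysis layer (phase histograms, mode-locking detection, interburst
    maps, slow-variable reset diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
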