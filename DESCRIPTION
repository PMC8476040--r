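Package: pottslatch
Title: Potts Attractor Networks for Latching Dynamics and Short-Term Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cortical latching dynamics in a Potts attractor neural
    network and uses them as a model of short-term memory recall. Provides
    generators for sparse random Potts patterns with their correlation and
    distance statistics, diluted Hebbian tensor couplings, four short-term
    memory "boost" mechanisms (local feedback, adaptive-threshold reduction,
    and two synaptic-potentiation variants), a heteroassociative extension for
    serial recall, a compiled integrator for the firing-rate equations with
    dual-timescale inhibition, digitization of overlap trajectories into
    retrieval sequences, the full family of free-recall and serial-recall
    performance metrics, information-theoretic sequence analysis, and
    closed-form capacity estimates with random-walk and greedy-similarity
    null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
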