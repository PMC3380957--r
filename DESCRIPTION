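Package: stpfilter
Title: Frequency-Dependent Filtering by Short-Term Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic and deterministic models of short-term synaptic
    depression by neurotransmitter vesicle depletion, together with the
    closed-form spectral theory of the synaptic filter they induce:
    steady-state moments, gain, the depression kernel, auto- and
    cross-spectra of the vesicle release train and postsynaptic
    conductance, coherence, and the coherence-based linear information
    rate. Includes generators for Poisson, correlated-population and
    doubly stochastic (rate-coded) presynaptic spike trains, event-driven
    exact simulation of vesicle release and recovery, Welch cross-spectral
    estimators with jackknife confidence bands for validating the closed
    forms against simulation, and pre-built experiment recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
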