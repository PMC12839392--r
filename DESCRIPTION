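Package: gustnet
Title: Multiscale Simulation of Gustatory Transduction and Spiking Taste Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end simulator of taste perception: tastant concentration
    vectors drive biophysical taste receptor cells (Goldman-Hodgkin-Katz ion
    currents for salty/sour, Hill-type metabotropic receptor kinetics for
    sweet/bitter, classical Hodgkin-Huxley membrane dynamics), whose spike
    trains feed a feedforward network of Izhikevich neurons coupled by
    glutamatergic synapses with phosphorylation-dependent AMPA receptor
    conductances. Synaptic receptor counts are trained with a genetic
    algorithm against information-theoretic objectives (hedonic-distance
    preservation and pure/mixed taste discrimination), while phosphorylation
    adapts online through a spike-synchrony plasticity rule. Includes
    stimulus generators, spike-pattern entropy quantification, a
    nearest-centroid taste decoder, and parameter-perturbation robustness
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
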