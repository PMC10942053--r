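Package: aisnav
Title: Sodium Channel Distributions in the Axon Initial Segment and Backpropagation Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multicompartment conductance-based modelling of how the spatial
    separation of NaV1.2 and NaV1.6 channels along the axon initial segment
    (AIS) shapes the threshold for action-potential backpropagation under
    somatic (orthodromic) versus axonal (antidromic) current-pulse
    stimulation. Provides a reduced layer-5 pyramidal cell generator with
    Hodgkin-Huxley style kinetics, explicit intra- and extracellular Na+, K+
    and Cl- concentration dynamics with Nernst reversal potentials, a
    Na+/K+ pump and longitudinal diffusion, an implicit branched-cable
    integrator, parameterised tanh density profiles for the two NaV
    subtypes, shift-clamp sensitivity analysis of individual gating
    properties, and bisection search for backpropagation and
    forward-propagation threshold currents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
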