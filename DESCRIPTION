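Package: predcortex
Title: Self-Supervised Predictive Learning in a Laminar Cortical Microcircuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-based model of the neocortical L4 - L2/3 - L5 microcircuit in
    which superficial layer 2/3 learns, by temporal self-supervision, to predict
    the deep layer 5 encoding of incoming sensory input from delayed L4 input and
    top-down context. Provides the forward dynamics with dendritic attenuation and
    knockout switches, manually specified plasticity rules with reconstruction
    gradient blocking and symmetric/random/absent error feedback, generators for
    contextual Gabor sequences and visuomotor speed/flow streams (with noise,
    occlusion, positional-shift and mismatch manipulations), and an analysis
    battery: linear decoding, principal-component profiles, Treves-Rolls
    population sparseness, per-neuron mismatch errors with baseline subtraction,
    simulated stimulation, and a denoising-autoencoder reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    nnet,
    e1071,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
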