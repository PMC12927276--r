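Package: whorfnet
Title: Brain-Constrained Spiking Network Simulations of Color-Label Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a brain-constrained spiking neural network of twelve
    frontotemporal-occipital cortical areas learning color percepts and spoken
    word forms under Hebbian long-term potentiation and depression. Implements
    perceptual pre-exposure and language-specific (one-label versus two-label)
    color-term learning protocols, cell-assembly extraction, representational
    similarity analysis, shared/unique neuron decomposition, and a mismatch
    negativity proxy based on unique-neuron responses, so that label-driven
    expansion or contraction of overlapping color representations can be
    studied at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    tools,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
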