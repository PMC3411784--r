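Package: avring
Title: Recurrent Ring-Network Model of Audio-Visual Spatial Integration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-layer firing-rate neural network of auditory and
    visual space, with Mexican-hat lateral connectivity, one-to-one excitatory
    inter-area connections, and Hebbian plasticity of the lateral synapses
    under synaptic normalization. The model reproduces the ventriloquism
    effect (online visual capture of perceived sound location) and the
    ventriloquism aftereffect (an enduring shift of unimodal sound
    localization after adaptation to a consistent audio-visual disparity).
    Provides population-vector, barycenter and winner-takes-all decoders on
    the circular space, protocol runners for unimodal controls, bias-versus-
    disparity sweeps, sensitivity analyses, cross-modal training paradigms
    and post-training tests, plus configuration and result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
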