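Package: memoryfoam
Title: Plastic Energy Landscapes for Online Unsupervised Category Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a gradient dynamical system whose energy landscape is
    continuously dented by incoming stimuli and relaxes back by an elasticity
    (forgetting) term, like memory foam. Streams of scalar or vector stimuli
    carve local minima that act as memorised categories; new inputs are
    recognised by resetting the state to the stimulus and descending the
    gradient. Provides grid-based and exact mesh-free landscape integrators,
    random-restart minima discovery, synthetic stimulus generators with
    closed-form ground truth (i.i.d. bimodal, overdamped Langevin double-well,
    jittered three-note melodies), a monophonic pitch-tracking front end
    (short-time Fourier peak extraction, resampling, delay embedding), polygon
    visualisation of vector stimuli, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
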