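Package: figground
Title: Figure-Ground Stimulus Synthesis, Encoding Models, and Segmentation Modulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying figure-ground segmentation in visual cortex:
    synthesis of texture- and opponent-motion-defined figure stimuli (Cross,
    Iso, and naturalistic 1/f conditions, morph schedules, static controls),
    a synthetic population generator built on a linear-nonlinear Gabor
    encoding model with an optional divisive orientation-tuned surround and a
    mean-scaled Gaussian noise model, spike-triggered-average receptive field
    estimation with 2D Gaussian fits and shuffle-based significance,
    per-neuron figure maps with cross-session cell matching, figure-ground
    and border-ownership modulation indices with bootstrap nulls, and
    cross-validated ridge decoding of figure position from population
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
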