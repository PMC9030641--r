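Package: cyborgmoth
Title: Fuzzy Deep Learning for Noninvasive Cyborg Moth Flight Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learning stack for closed-loop, light-stimulated insect flight
    control. Provides interval-valued Pythagorean fuzzy numbers with their
    distance measures and operational laws; denoising autoencoder layers whose
    weights are fuzzy numbers, pretrained layer-wise with the water wave
    optimization metaheuristic; Pythagorean fuzzy c-means clustering for
    grouping individuals by stimulus-response profile; a three-hierarchy
    behavior learner (species-common, group-specific, individual-specific)
    predicting seven flight parameters from 80 stimulus, ambient, and history
    variables; and an inverse control learner recommending ultraviolet-lamp
    stimuli that elicit required flight behavior. A seeded synthetic cohort
    generator emulates the statistical structure the learners assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
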