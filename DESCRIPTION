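Package: activegaze
Title: Active-Inference Simulation of Gaze During Action Observation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an observer that watches synthetic reach-to-grasp
    movies and infers the actor's goal (power grasp of a big object versus
    precision grip of a small object) by sequential Bayesian hypothesis
    testing. Forward sub-models of hand position and hand preshape are
    echo-state reservoirs with Bayesian linear readouts giving Gaussian
    predictive distributions; saccades are directed to the most informative
    locations of a belief-weighted salience map combining epistemic value
    (expected information gain) with hand- and object-centred components.
    Includes a synthetic dataglove/movie generator, a 2x2
    (preshape x target) experiment harness with signed arrival-time
    analysis, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
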