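Package: hage
Title: Protocol Engine, Participant Simulator and Longitudinal Analysis for
    Remote Unsupervised Memory Testing
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A headless toolkit for digital phenotyping of long-term memory
    with spatial-alternation and image-change tasks delivered at randomised
    inter-trial intervals. Implements the task protocol (activation
    scheduling, alternation rule state machines, image-change generation,
    button semantics, scoring and an error taxonomy), a generative
    synthetic-participant simulator (inter-trial-interval dependent
    forgetting, lapses, win-stay practice drift, miss-dominated change
    detection, engagement and dropout), and the cohort analysis pipeline:
    ITI-binned performance curves, inclusion and outlier filtering,
    adherence surfaces, win-stay/win-shift practice effects, a
    repeated-measures ANOVA with Greenhouse-Geisser correction, and
    chance-level estimation for the image tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
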