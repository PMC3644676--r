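Package: ctlearn
Title: Continuous Tracking Analysis for Implicit Motor Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.com")
Description: Tools for studying implicit sequence-specific motor learning with
    the continuous tracking (CT) task. Synthesizes repeated and random
    sinusoidal-series target segments with difficulty-equating screens,
    decomposes joystick tracking into overall error (RMSE), temporal
    precision (cross-correlation time lag) and spatial accuracy, aggregates
    sequence-specific difference scores with repeated-measures ANOVA and
    explicit-recognition scoring, fits block-design fMRI GLM contrasts, and
    builds behaviorally weighted group correlation images with cluster-extent
    thresholding. A seeded cohort simulator with known ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
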