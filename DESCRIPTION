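Package: gaitlen
Title: Step Length Estimation from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stride segmentation, step-length estimation models, and
    evaluation tools for pedestrian dead reckoning with body-worn
    accelerometers.  Implements an adaptive step-length model driven by
    stride frequency and the range of acceleration magnitude, four
    published comparison models, least-squares calibration of tunable
    constants, a per-walking-speed adaptive constant selector, optical
    marker kinematics with heel-strike reference stride lengths, a
    canonical-correlation stage for ranking candidate gait predictors,
    and seeded synthetic gait generators so the whole pipeline can be
    exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
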