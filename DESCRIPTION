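Package: posturekit
Title: Wearable Necklace Posture Monitoring Without the Hardware
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hardware-free implementation of the computation inside a
    smart-necklace posture monitor: moving-average filtering of triaxial
    accelerometer traces, hysteresis-comparator posture assessment with
    throttled reminder events, skeletal-keypoint auto-calibration of the
    wearer's standard values, threshold derivation from clinician-labeled
    tilt measurements, slider-based manual fine adjustment, and a synthetic
    wearer simulator that turns scripted pitch/roll maneuvers into
    accelerometer traces and matching keypoint streams so the whole
    pipeline can be exercised and tested without a sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
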