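Package: prefall
Title: Pre-Impact Fall Detection Modelling for Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating pre-impact fall detection
    models from body-worn inertial measurement units (IMUs), with an emphasis
    on cohort-specific (post-stroke versus control) model training. Provides a
    parametric synthetic generator of multi-sensor accelerometer/gyroscope
    recordings of falls, near-falls and activities of daily living; zero-phase
    Butterworth band-pass preprocessing, impact detection and
    lead-time-anchored window extraction; per-channel statistical feature
    extraction; an adaptive-boosting (SAMME decision-stump) classifier with
    leave-one-subject-out, control-trained and severity-stratified
    leave-one-group-out evaluation schemes; lead-time optimisation sweeps; and
    paired model comparison with Holm-Bonferroni family-wise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
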