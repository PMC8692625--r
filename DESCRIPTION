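Package: bedsignals
Title: Passive Weight and Cardiopulmonary Monitoring from Under-Bed Force Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Algorithms for adherence-independent physiological monitoring from
    multi-channel force sensors placed beneath the legs of a bed: joint
    calibration of load cells and continuous total-body-weight estimation,
    step-event detection and per-person weight attribution when a bed is
    shared, respiratory waveform compositing by sliding-window principal
    component analysis with breath-peak rate estimation, apnea detection and
    central/obstructive classification, ballistocardiogram-derived heart rates
    and beat-amplitude analytics (respirophasic coupling, post-ectopy
    augmentation), two-person respiratory source separation with a
    linear-Gaussian state-space model fitted by expectation-maximization and
    Kalman smoothing, and longitudinal epoch aggregation with plausibility
    filtering and heatmap exports. Includes a seeded synthetic bed-signal
    simulator with full ground truth so every stage is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
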