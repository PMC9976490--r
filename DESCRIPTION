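Package: esrkit
Title: Simulation and Analysis of Stimulation-Evoked Epidural Spinal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing epidural spinal recordings (ESR) made during
    epidural electrical stimulation from multi-contact leads. Provides a
    synthetic-data generator for stimulation-evoked sessions (propagating
    evoked compound action potentials, common-mode stimulation artifact and
    myogenic (EMG) components, additive noise), virtual re-referencing
    (local tissue, differential, and on-lead reference schemes), the standard
    band-pass filtering and grouped median-waveform averaging, feature
    extraction (negative-peak latency, peak-to-peak amplitude, rectified
    area-under-the-curve, dose-response curves and detection thresholds),
    regression-based conduction-velocity estimation with fiber-type
    classification, propagation-based discrimination of neural from
    common-mode components, and between-session feature comparison for lead
    migration detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
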