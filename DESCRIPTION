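Package: drowsyEEG
Title: Context-Aware Driver Drowsiness Detection from EEG and Head Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and classification pipeline for early detection
    of driver drowsiness from a single bipolar occipital EEG channel fused with
    a three-axis head-mounted gyroscope. Provides causal Butterworth band-pass
    (4-30 Hz) and 60 Hz notch filtering, 2-s epoch segmentation, FFT relative
    band power (theta/alpha/beta) and gyroscope movement-power features,
    one-minute window averaging against video-based ground-truth labels,
    soft-margin SVM classification (linear and RBF kernels) with
    leave-one-subject-out cross-validation and C/g grid optimisation, ROC-area
    feature discriminability screening, and a calibrated synthetic-cohort
    generator that emulates a one-hour simulated-driving experiment including
    movement-artifact contamination of the EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
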