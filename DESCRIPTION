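Package: mwdetect
Title: Individual-Level Detection of Mind Wandering from EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for detecting self-reported mind wandering from
    multichannel EEG recorded during probe-based naturalistic sessions
    such as live lectures. Implements continuous-signal conditioning
    (robust bad-channel screening, common-average referencing,
    exponentially weighted running standardization, linear-phase FIR
    bandpass filtering), two-stage artifact handling (cross-validated
    peak-to-peak epoch rejection followed by extended-infomax ICA with
    skewness/kurtosis component thresholding), probe-locked epoch
    extraction, per-band common-spatial-pattern feature learning with a
    non-linear support vector machine, probe-grouped and
    leave-one-subject-out cross-validation, permutation calibration of
    chance-level F1 scores, and two-factor repeated-measures ANOVAs on
    band power with partial eta squared effect sizes. A forward-model
    synthetic-session generator with known ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
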