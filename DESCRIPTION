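Package: emgesture
Title: Real-Time Hand-Gesture Recognition from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end myoelectric pattern-recognition pipeline for
    8-channel surface electromyography (sEMG) armband recordings sampled at
    200 Hz: envelope preprocessing (normalization, rectification, 4th-order
    Butterworth low-pass, spectral muscle-activity detection), dense
    sliding-window time-domain feature extraction (mean absolute value, root
    mean square, a slope-sign-change statistic, waveform length, and the
    Hjorth activity, mobility and complexity parameters), a single-hidden-layer
    feedforward neural network trained by full-batch gradient descent with a
    cross-entropy cost, and a streaming activation-threshold vote rule that
    commits to a gesture while it is still being performed.  Includes a
    synthetic multichannel sEMG session generator with known gesture onsets,
    an evaluation harness (confusion matrices, per-class sensitivity and
    precision, response-time summaries, window-size and threshold sweeps),
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
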