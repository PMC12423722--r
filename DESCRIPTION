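Package: wristpwv
Title: Brachial-Ankle Pulse Wave Velocity Estimation from Wrist PPG and ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates brachial-ankle pulse wave velocity (baPWV) from
    time-aligned wrist photoplethysmography (PPG) and single-lead ECG.
    Implements wavelet baseline correction and powerline notch filtering,
    cycle segmentation with a cycle-length signal quality index, fiducial
    detection on the PPG and its first and second derivatives (SDPPG a-f
    points), weighted pulse decomposition into five Gaussian component
    waves with a reconstruction-error quality gate, a feature stack with
    systematic ratio combination, multivariable baseline regressions, and
    a hierarchical classify-then-regress estimator with overlapping
    training zones around the subdivision boundary. A synthetic-data
    module generates PPG/ECG records and cohorts with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
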