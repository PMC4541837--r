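Package: migrainecast
Title: Per-Patient Migraine Forecasting from Ambulatory Wearable Signals
Version: 0.1.0
Authors@R:
    person("Migrainecast", "Developers", email = "maintainers@migrainecast.org",
           role = c("aut", "cre"))
Description: Tools for building per-patient migraine prediction models from
    multi-rate wearable recordings (skin temperature, electrodermal activity,
    heart rate derived from ECG, and pulse oximetry). Provides a synthetic
    ambulatory-patient generator with known ground truth, preprocessing
    (FIR-decimator synchronization to a one-minute grid, Gaussian-process
    gap filling, R-peak heart-rate extraction), a two-semi-Gaussian
    symptomatic pain-curve model, subspace (N4SID) state-space
    identification with k-step-ahead prediction, cross-validated ensemble
    ranking with false-positive repair, event-based scoring (TPR/PPV/F-score),
    sensor-fault robustness suites and a sensor-availability-aware model
    selection hierarchy, plus an end-to-end study workflow and command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
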