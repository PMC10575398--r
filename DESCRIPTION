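Package: emophysio
Title: Emotion and Arousal Classification from Wearable ECG and EDA Signals
Version: 0.1.0
Authors@R: person("emophysio", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-branch pipeline for affective-state analysis of wearable
    physiological recordings. The electrodermal branch cleans skin-conductance
    level (SCL) traces (cubic-spline gap filling, zero flooring) and detects
    emotional-stimulus trigger marks from peaks of the smoothed second
    derivative. The cardiac branch down-samples ECG, removes raw-signal
    outliers with a sliding-window min/max rule, extracts R peaks and RR
    intervals, cleans the RR series with a generalized extreme Studentized
    deviate test plus modified Akima interpolation, and computes eight
    time- and frequency-domain heart-rate-variability features (RMSSD, SDNN,
    mean RR, HR, and Lomb-Scargle HF/LF/VLF band powers with the HF/LF
    ratio). Emotion-versus-rest state is classified with a Gaussian-kernel
    support vector machine; arousal strength (low/mid/high from 9-point SAM
    self reports) is classified from Morlet continuous-wavelet-transform
    scalogram images with a small convolutional network trained with a
    class-weighted cross-entropy loss. A synthetic-session generator with a
    configurable stimulus/rest/recall protocol, stage-dependent heart-rate
    effects, phasic skin-conductance responses and injectable artifacts
    makes every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
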