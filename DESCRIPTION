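Package: capcri
Title: Cardiopulmonary Resonance Indices for Sleep CAP Detection and Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies respiratory sinus arrhythmia as spectral Granger
    causality from respiration to RR intervals, extracts cardiopulmonary
    resonance indices (resonance frequency, amplitude, bandwidth, quality
    factor and resistance) in sliding windows, and uses them together with
    heart-rate-variability, body-movement and Markov-stability features to
    classify 30-second sleep epochs into the 18 sleep/CAP states (wake, REM,
    and A1/A2/A3/non-A phases within NREM stages S1-S4) with a two-layer
    random forest, and to diagnose insomnia and narcolepsy at the subject
    level with a support vector machine. Includes preprocessing for ECG,
    respiration and chest-acceleration channels (beat detection, RR-interval
    cleaning, wavelet baseline removal, respiration quality gating), a
    seeded synthetic polysomnography simulator for the three subject groups,
    evaluation metrics and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    e1071,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
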