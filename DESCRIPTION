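Package: vocmotor
Title: Event-Locked Analysis of Infant Motor-Vocal Coupling from Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying the temporal coupling between infant
    vocalisations and limb movement recorded with body-worn accelerometers.
    Reads session audio (WAV), utterance annotations (Praat TextGrid) and
    3-axis accelerometer tables; synchronises audio and sensor clocks via a
    hand-clap event; preprocesses limb acceleration (gap interpolation,
    resampling, vector magnitude, Butterworth highpass); extracts
    vocalisation-locked envelope epochs with envelope-based baseline
    correction; summarises per-window median acceleration; and fits linear
    mixed-effects models with Satterthwaite tests, estimated-marginal-mean
    contrasts and Cohen's f effect sizes. A synthetic dyad-session generator
    with known ground truth makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    Matrix,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
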