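Package: alphacross
Title: Simulation and Analysis of Crossover tACS Studies of EEG Alpha Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for sham-controlled crossover studies of
    individual-alpha-frequency transcranial alternating current stimulation
    (tACS) during a continuous performance task. Generates complete synthetic
    sessions (22-channel EEG with 1/f background and a posterior alpha
    oscillator, letter-stream task schedules and keypress logs, gaze label
    streams, head-tracking trajectories and stimulation waveforms), and
    analyzes them: individual alpha frequency detection from resting EEG,
    artifact-robust Morlet wavelet alpha power with spherical-spline channel
    interpolation, omission/commission/reaction-time-variability scoring,
    gaze dwell-time and composite distractibility metrics, head actigraphy,
    2x2 within-subject ANOVA with partial eta squared, Bonferroni post-hoc
    paired tests and noncentral-F power analysis for the within-between
    interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
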