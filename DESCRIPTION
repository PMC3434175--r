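Package: cuepool
Title: Psychometric Thresholds, Cue Pooling and Heave-Simulation Fidelity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for human-performance-centred fidelity evaluation of
    multisensory simulated environments. Fits Weibull psychometric functions
    to forced-choice motion-categorisation trials by maximum likelihood and
    extracts 81%-correct detection thresholds; combines unimodal and bimodal
    thresholds under the Quick pooling model and estimates the Minkowski
    cue-combination exponent k, classifying integration as linear, optimal,
    probability summation or independent; simulates mechanistic ideal
    observers realising each integration regime; simulates a single-axis
    heave flight-dynamics model with calibrated auditory and kinematic cue
    channels, sum-of-sinusoids target paths and closed-loop synthetic pilots;
    and provides the tracking-performance statistics (median absolute error,
    factorial main effects, repeated-measures ANOVA, paired comparisons and
    a learning-curve inclusion filter) used in transfer-of-training analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
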