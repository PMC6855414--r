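Package: sleepcrit
Title: Critical Dynamics of Theta- and Delta-Burst Micro-Architecture in Cortical EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to analyse the burst micro-architecture of cortical EEG across
    the sleep-wake cycle. Extracts theta- and delta-bursts from the windowed
    ratio of theta to delta Welch band power, characterises burst-duration
    statistics (power law, Weibull, generalized Gamma) with weighted
    least-squares fits and binomial error bars, tests scale invariance through
    finite-size-style data collapses over threshold and window size, analyses
    quiet-time self-similarity, quantifies long-range correlations with
    detrended fluctuation analysis, tests anti-correlated coupling between
    consecutive bursts with rank statistics and shuffling surrogates, and
    implements a phenomenological Gaussian-rank pairing model of burst coupling
    with majority-rule coarse-graining. Includes seeded generators for
    synthetic duration sequences, fractional Gaussian noise and EEG-like
    signals so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
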