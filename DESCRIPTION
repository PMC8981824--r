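Package: eegmicrostate
Title: Resting-State EEG Microstate Segmentation, Back-Fitting and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete resting-state EEG microstate analysis pipeline:
    global field power (GFP) computation, extraction of topographies at GFP
    peaks, polarity-invariant modified K-means clustering into the four
    canonical microstate classes A-D, permutation-based aggregation of
    subject maps into group maps, canonical labelling, back-fitting of the
    continuous record, and the standard temporal parameters (mean duration,
    occurrence, time coverage) and transition-syntax percentages.  Group
    comparisons cover mixed-design ANOVA with Greenhouse-Geisser correction,
    simple effects, Bonferroni-corrected transition t-tests, topographic
    analysis of variance (TANOVA) by randomization, chi-square and Pearson
    correlation helpers.  A synthetic-EEG generator plants known semi-Markov
    microstate dynamics, scalp topographies on a standard 10-10 montage and
    a clinical score correlated with a microstate parameter, so that every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
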