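Package: perceptseg
Title: Perceptual Segmentation Maps from Same/Different Cue-Pair Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how observers perceptually segment
    images, using trial-based same/different judgments about pairs of cued
    locations. Reconstructs probabilistic segmentation maps by penalized
    maximum likelihood, derives per-cell entropy (perceptual uncertainty)
    maps, and quantifies map similarity with a mutual-information based
    Information Gain statistic calibrated against a spatial-shuffle
    permutation null. Companion analyses cover reaction-time learning
    curves (bootstrap medians and an exponential trial-constant fit),
    eye-tracking gaze density and image-coverage curves, and trial-locked
    EEG statistics (ERPs, Global Field Power, pointwise significance
    windows, and cluster-based permutation tests). A seedable synthetic
    observer, gaze, and EEG generator makes the full pipeline testable
    end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    igraph,
    yaml,
    withr,
    minpack.lm,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
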