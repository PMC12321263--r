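Package: perflex
Title: Quantification of Proboscis Extension Behavior and Gustatory Neuron
    Activity in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying odor- and taste-evoked
    proboscis extension reflex (PER) in tethered flies and the gustatory
    receptor neuron (GRN) activity that drives it. Computes proboscis joint
    angles from markerless pose-tracking landmark tables, detects PER and
    partial extensions by threshold and hysteresis rules on the rostrum and
    haustellum angles, derives per-trial and per-fly behavioral metrics,
    and compares extension trajectories with band-constrained dynamic time
    warping, K-medoids clustering and elbow model selection. Also registers
    multi-plane two-photon calcium movies by correlation maximization,
    extracts ROI delta-F/F traces and windowed peak responses, counts
    spikes from taste-sensillum tip recordings, fits the linear model
    relating sweet and bitter GRN responses to PER magnitude, and provides
    the Scheirer-Ray-Hare rank-based two-factor test. Synthetic-data
    generators with known ground truth emulate all input modalities so
    every stage is testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
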