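Package: prfsize
Title: Linking Population Receptive Field Architecture to Perceptual Size Biases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the spatial tuning of early visual
    cortex relates to idiosyncratic biases in perceived object size.
    Implements a four-alternative perceptual matching (MAPS) task
    simulator and its detector-model analysis, a Gaussian filter-bank
    population read-out model of size estimation (including Delboeuf
    illusion stimuli), a population receptive field (pRF) forward model
    with two-gamma haemodynamic response estimation and two-stage
    (coarse grid plus simplex) fitting, eccentricity-band summaries of
    cortical architecture, and the statistical battery relating
    behavioural biases to cortical predictors, together with Monte
    Carlo power and false-positive calibration of those tests. A
    synthetic-data generator produces coupled behavioural and cortical
    data sets so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
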