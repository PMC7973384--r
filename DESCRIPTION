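Package: hypnocycle
Title: Hypnodensity Correlation Analysis of Sleep-Cycle Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing sleep architecture from hypnodensity
    series, i.e. time series of per-epoch probability distributions over
    the five AASM sleep stages (Wake, N1, N2, N3, REM).  Implements
    vectorial auto- and cross-correlation of 5-dimensional stage
    probability vectors, peak detection on the resulting correlation
    curves and estimation of individual ultradian sleep-cycle period
    lengths, including a windowed variant for non-stationary period
    tracking.  Quantifies class separability of labelled embeddings with
    the generalised discrimination value (GDV), projects embeddings with
    metric multidimensional scaling, and draws hypnodensity graphs,
    correlation curves and GDV profiles.  A synthetic-data module
    generates cyclic hypnograms, softmax-like noisy hypnodensities,
    multi-channel variants with stage biases, Gaussian cluster
    embeddings and toy stage-signatured EEG, so every analysis is
    testable without access to clinical polysomnography data.  A
    reduced-scale convolutional/recurrent sleep-stage classifier closes
    the loop from raw signal to hypnodensity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
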