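Package: rankseq
Title: Rank-Order Sequence Coding Analysis for Population Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-specific response sequences in
    multi-channel spiking activity: spike detection from filtered broadband
    traces, sliding-window firing-rate estimation, per-channel peak and onset
    latency extraction, latency-sequence parameterization (span and center),
    rank-order template-matching and Gaussian naive-Bayes population decoding
    with stratified cross-validation, time-resolved decoding decay slopes,
    population state-space trajectory analysis (PCA projection, native-space
    distances, discriminability index), a 250-neuron Izhikevich recurrent
    spiking network with multiplicative spike-timing-dependent plasticity, and
    a synthetic multi-unit-activity generator that emulates ramped visual
    stimulation so every stage is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    knitr
Config/testthat/edition: 3
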