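Package: xiirhythm
Title: Burst-Rhythm Analysis of Hypoglossal Nerve Recordings with a
    Burstlet-Train Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects inspiratory-like bursts in integrated hypoglossal (XII)
    nerve rootlet recordings from rhythmic brainstem slice preparations and
    quantifies drug-induced changes in burst period, height, width, area and
    period irregularity. Provides trace conditioning (decimation, Hampel
    artifact removal, rectified leaky integration), prominence-based burst
    detection, per-epoch baseline normalization, Smirnov-Grubbs outlier
    screening, Hartigan's dip test of burst-period multimodality with
    Gaussian-mixture mode decomposition, and Gaussian generalized estimating
    equations with Bonferroni-adjusted contrasts for repeated-measures group
    inference. Includes a receptor-occupancy dose-response model for
    prostanoid (EP2/EP3) modulation of the burst period and a synthetic
    burstlet-train recording generator with transmission dropout that
    provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    boot,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
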