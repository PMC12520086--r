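Package: ptsynergy
Title: Pattern-Temporal Synergy Analysis of Multichannel Physiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Pattern-Temporal Synergy (PTS) index, a composite,
    surrogate-calibrated measure of reflexive coherence in multichannel
    physiological time series such as plant calcium, phloem-voltage, oxygen
    micro-flux and heat-flux recordings. Provides sliding-window estimators of
    five pattern proxies (active information storage, Louvain modularity,
    partial-information-decomposition synergy, symbolic transfer entropy and
    the aperiodic 1/f spectral slope), phase-randomized and iterated
    amplitude-adjusted Fourier surrogate null models, phase-locking and
    weighted phase-lag-index coherence gating, epoch-level dual-gate
    classification, preregistered baseline/collapse/recovery decision logic,
    and a seeded simulator of coupled-oscillator recordings with
    anesthetic-collapse and wash-out regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    zoo,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
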