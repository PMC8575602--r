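Package: eegtda
Title: Persistent-Homology Analysis of EEG Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological analysis of multichannel EEG evoked by two stimulus
    conditions. Builds per-trial functional connectivity from band-limited
    epochs, either as phase-locking value (PLV) matrices via the analytic
    signal or as standardized squared Euclidean distance matrices, sweeps a
    Vietoris-Rips filtration over the normalized connectivity weights,
    computes persistence barcodes by boundary-matrix reduction over GF(2),
    and derives Euler-characteristic curves with their topological
    phase-transition point as well as persistent-entropy features. A seeded
    synthetic EEG generator with condition-dependent inter-channel phase
    coherence makes the full pipeline testable end to end, and a
    leave-one-trial-out threshold classifier quantifies how well persistent
    entropy distinguishes the two conditions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
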