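Package: imcohnet
Title: Imaginary-Coherence Functional Connectivity and Multiscale Brain
    Networks for Tactile EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates sensor-space EEG functional connectivity with the
    imaginary part of coherency, extracts stimulation-induced connectivity
    by a cluster-based permutation test on channel-pair statistics, builds
    per-subject binary functional brain networks by FDR-thresholded paired
    t-tests, and computes multiscale graph indices (global and local
    efficiency, smallworldness, inter- and intra-hemispheric density and
    degree) together with hemispheric-lateralization summaries and group
    statistics. Includes a deterministic synthetic-cohort generator with
    planted phase-lagged beta-band coupling and zero-lag volume-conduction
    mixing, EDF and delimited-matrix I/O, and the signal-conditioning chain
    (zero-phase band-pass, average reference, epoching, mid-sagittal flip).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
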