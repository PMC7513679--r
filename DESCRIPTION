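Package: dyadsync
Title: Inter-Brain Coherence and Dyadic Power-Pattern Analysis for Dual-EEG Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-EEG (hyperscanning) recordings of
    two-person teams performing segmented coordination tasks. Implements
    complex Morlet wavelet decomposition on a 15-40 Hz grid, sliding-window
    phase-locking values aggregated into intra- and inter-brain coherence,
    trimmed correlations of coherence with a behavioral leader-readiness
    measure, distance-based mining of dyadic wavelet-power patterns specific
    to high versus low team coordination, spectral reordering of electrode
    correlation matrices, and cross-frequency asymmetry analysis of
    inter-subject power correlations. A coupled-oscillator synthetic dual-EEG
    generator with a ground-truth ledger makes every stage testable without
    access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
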