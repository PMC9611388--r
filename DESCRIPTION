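Package: eegplv
Title: Occipital-Seeded Phase-Locking Connectivity and Event-Related
    Spectral Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for event-related EEG analysis centred on phase-locking
    value (PLV) functional connectivity from a fused occipital seed to all
    scalp electrodes, with a bootstrap-against-baseline screen that retains
    only "effective" PLVs (ePLVs).  Includes Monte-Carlo permutation and
    paired bootstrap tests with an exhaustive-enumeration oracle, a
    zero-phase frequency-domain bandpass filter, AMUSE second-order blind
    source separation for ocular-artifact removal, Morlet-wavelet
    event-related spectral perturbation (ERSP) with a Hjorth-style surface
    Laplacian, mu-rhythm ERD/ERS extraction, parieto-occipital ERP
    lateralization analysis, and a synthetic multichannel EEG generator
    with known ground-truth coupling, power modulation, ERPs and artifacts
    for end-to-end validation.  Recordings round-trip through 16-bit EDF
    with a sidecar event table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
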