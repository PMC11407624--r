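Package: ssvepbmi
Title: Stimulus Design, Simulation and Frequency Detection for SSVEP Brain-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state visual evoked potential (SSVEP)
    brain-machine interfaces: frame-based flicker stimulus design under a
    fixed display refresh rate (duty-cycle binning, square-wave harmonic
    spectra, viewing geometry, stimulus signal-to-noise ratio), generation
    of synthetic multi-channel EEG sessions with realistic trial structure
    and spectral phenomenology, preprocessing (zero-phase filtering,
    trial segmentation, SNR-based channel selection), frequency detection
    by power spectral density analysis (PSDA), canonical correlation
    analysis (CCA) and filter-bank CCA (FBCCA), and evaluation (accuracy
    over window length, confusion matrices, information transfer rate,
    paired condition comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
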