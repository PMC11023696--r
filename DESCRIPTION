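Package: vasoentrain
Title: Vasomotion Entrainment Analysis from Fluorescence Shadow Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies slow (~0.25 Hz) vasomotion and its entrainment to an
    oscillating visual stimulus from fluorescence recordings. Provides vessel
    cross-section profiling with full-width-at-10%-maximum diameter readout,
    detection of spontaneous vasodilation events, photobleach-robust percent
    normalization, amplitude spectra and spectrograms with a stimulus-locked
    peak-ratio statistic (PR0.25) including a pixelwise map, cross-correlation
    phase-lag estimation between channel pairs, optokinetic-response (HOKR)
    eye-movement gain analysis, and a synthetic-data module that generates
    every input with stored ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
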