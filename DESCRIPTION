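Package: decalQC
Title: Quality Scoring of Bone Decalcification Protocols from Raman and
    Multimodal Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for comparing bone-decalcification
    protocols by Raman microspectroscopy and multimodal scoring.  Provides
    Raman hyperspectral preprocessing (silicon-band wavenumber calibration,
    automated cosmic-ray removal, SNIP and rubber-band baseline correction,
    mean normalization, median spectra), N-FINDR endmember extraction with
    non-negative least-squares abundance maps and false-colour imaging, a
    four-step signal-to-noise statistic anchored in the spectroscopically
    silent region, phosphate-band detection of residual bone mineral, a
    signal-intensity index for fluorescence acquisition settings, and the
    multi-observer, multi-batch score-aggregation scheme used to rank
    decalcifiers across imaging modalities.  A seeded synthetic-data
    generator emulates calcified and decalcified bone spectra, bone-marrow
    scans and observer score tables so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
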