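Package: ftirserum
Title: Reagent-Free Multi-Analyte Serum Quantification from FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and prediction tools for quantifying a 38-analyte
    serum panel from mid-infrared absorbance spectra of dried serum films.
    Implements the full chemometric workflow: spectral preprocessing
    (replicate averaging, two-point baseline correction, straight-line
    excision of atmospheric CO2 bands, vector normalization), detection of
    stable absorption bands with extraction of peak absorbances and
    trapezoidal band areas, construction of a shared composite feature from
    correlation-screened multiplicative ratio terms with simplex-constrained
    weights fitted by a reduced-gradient least-squares solver, and
    per-analyte scale coefficients with a global multiplicative bias
    correction. Includes a synthetic dilution-study generator with a
    Gaussian band library for end-to-end validation against known ground
    truth, and packaged reference coefficient tables for a bovine
    control-serum panel.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
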