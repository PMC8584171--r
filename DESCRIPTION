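Package: ternafac
Title: PARAFAC Isolation of Interaction Factors from FTIR Spectra of
    Ternary Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting weak-interaction spectral factors from
    ATR-FTIR absorbance series of ternary peptide-model/water/osmolyte
    solutions. Implements interpolation of a scattered two-solute
    concentration design onto an evenly spaced grid by local plane fits,
    sequential subtraction of the water and single-solute contributions,
    concentration-derivative spectra of molar absorbance, and
    unconstrained trilinear (CP/PARAFAC) decomposition by alternating
    least squares with an incremental, redundancy-based rank-selection
    procedure. A synthetic-spectra generator with closed-form ground
    truth (Beer-Lambert band mixing, self-association and bilinear
    interaction terms, preparation jitter, detector noise) supports
    end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    interp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
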