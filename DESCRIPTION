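Package: nirseed
Title: NIRS Chemometrics for Thymoquinone Quantification in Intact Seeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Near-infrared reflectance (NIRS) chemometrics pipeline for
    quantifying thymoquinone in intact black cumin (Nigella sativa) seeds.
    Implements spectral preprocessing (standard normal variate, detrend,
    gap-segment derivatives), modified partial least squares (MPLS)
    calibration with grouped cross-validation and parsimonious factor
    selection, calibration/validation statistics (SEC, SECV, bias-corrected
    SEP, one-minus-variance-ratio), multi-year validation and calibration
    expansion strategies, top-fraction selection-predictability analysis,
    and wavelength-significance profiling from group-average spectra. A
    synthetic spectra generator with analyte-linked absorption bands, matrix
    constituents, scatter and season effects provides ground-truth data for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
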