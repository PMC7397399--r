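Package: dualflow
Title: Batch Processing of Dual-Channel GCxGC Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open, testable batch data-processing workflow for
    comprehensive two-dimensional gas chromatography (GCxGC) acquired with
    simultaneous quadrupole mass spectrometry (qMS) and flame ionization
    (FID) detection. Reads ANDI/AIA netCDF chromatograms, folds detector
    signals into the two-dimensional retention plane defined by the
    modulation period, performs dynamic baseline correction on the MS
    stream and TopHat morphological correction on the FID stream, detects
    and delineates 2D peaks, builds stencil region sets from MS data and
    transfers them onto FID data for quantification, and assembles
    zero-filled batch peak tables with unit-vector normalization,
    autoscaling, and principal component analysis. Includes a synthetic
    dual-channel sample generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ncdf4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
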