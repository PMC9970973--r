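Package: lsfmcoupling
Title: Oblique Light-Sheet Reconstruction and Calcium-Coupling Analysis
    for Cardiomyocyte Co-Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing electromechanical coupling between
    stem-cell-derived and adult cardiomyocytes imaged by oblique dual-channel
    light-sheet fluorescence microscopy. Provides a synthetic acquisition
    generator with known ground truth, detector-frame preprocessing
    (fixed-pattern-noise correction, spectral channel splitting, bead-based
    affine co-registration), reconstruction of sheared plane stacks into
    isotropic lab-frame volumes with orthogonal views and depth-coded maximum
    intensity projections, ROI-based dF/F0 calcium-transient extraction and
    event detection, rule-based classification of contracting, transient and
    coupled cells, and 2x2 contingency chi-square reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
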