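Package: scratchkin
Title: Scratch-Assay Image Quantification and Re-Epithelialization Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of fluorescence time-lapse scratch
    (wound-healing) assays based on single-nucleus recognition. Segments
    nuclei in per-well TIFF image series (block-minimum illumination
    correction, global Otsu thresholding, watershed declumping, diameter
    filtering), automatically detects the cell-free scratch band from the
    positional cell-frequency histogram at the first timepoint, counts
    cells inside and outside the band over time, and fits a modified
    Gompertz growth model by Levenberg-Marquardt nonlinear least squares
    to extract re-epithelialization kinetics: lag time (lambda, minutes),
    repair rate (mu_m, cells/minute) and plateau cell number (A).
    Poorly fitting wells (R-squared below 0.9) are flagged, and plate
    quality is summarised with the Z-prime factor. Includes a
    ground-truthed synthetic plate generator for validation and a
    command-line pipeline with TSV, PNG and HTML reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
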