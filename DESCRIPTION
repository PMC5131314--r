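Package: folliculometry
Title: Folliculometric Analysis of Light-Sheet Ovary Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative morphometry of ovarian follicles in 3D light-sheet
    (SPIM) image stacks of cleared ovary tissue. Provides a synthetic ovary
    phantom generator with voxel-accurate ground truth, multi-page TIFF stack
    I/O with physical voxel spacing, automated follicle/theca/lumen/COC
    segmentation with a manual-mask ingestion path, folliculometric
    measurements (volume, equivalent diameter, equatorial asymmetry, thecal
    wall thickness distributions, cumulus-oophorus-complex sizing),
    developmental staging, and per-stage cohort statistics with growth-curve
    and log-volume regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
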