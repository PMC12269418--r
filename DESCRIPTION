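Package: mvnquant
Title: Quantification of Cancer Intravasation into Microvascular Networks on a Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for microphysiological models of tumor-cell
    intravasation into self-assembled microvascular networks (MVNs) in
    microfluidic devices. Provides random-forest pixel classification of vessels
    from phase-contrast and GFP channels using a Weka-style image feature bank,
    spheroid-proximal region-of-interest extraction, co-localization-based
    counting of intravasated cancer particles with size and circularity filters,
    vascular network skeleton metrics (junctions, tubule length), microvascular
    permeability-coefficient estimation from dye-efflux time series, standard 2D
    assay quantifications (circularity, corrected total cell fluorescence,
    scratch gap area, spheroid invasion ratio, cytokine-array log2 fold change),
    and a calibrated synthetic-microscopy generator with machine-readable ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    ranger,
    jsonlite,
    matrixStats,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
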