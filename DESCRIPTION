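Package: cytocycle
Title: Label-Free Cell-Cycle Analysis for Imaging Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end label-free cell-cycle analysis from paired
    brightfield/darkfield single-cell images, as produced by imaging flow
    cytometers. Provides tiling of single-cell images into montages,
    label-free brightfield segmentation, extraction of a fixed, versioned
    213-feature morphological profile (size/shape, Zernike moments,
    intensity, radial distribution, Haralick texture, granularity
    spectrum), least-squares boosted regression of per-cell DNA content,
    random-undersampling boosted classification of mitotic phases, nested
    cross-validation, and Watson pragmatic deconvolution of DNA-content
    histograms into G1/S/G2M fractions. Includes a seeded synthetic
    image generator with known ground truth so the whole workflow can be
    exercised and validated without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    rpart,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
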