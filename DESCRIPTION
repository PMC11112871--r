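Package: fruitmorph
Title: Multi-View Fruit Morphometry from Calibrated Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated description of fruit appearance from five calibrated
    images per fruit (four side views, one top view). Segments each fruit
    against an empty-box background by combining an HSV threshold with
    background-difference Otsu thresholding, converts the resulting masks to
    360-degree polar radius profiles, corrects side views for mirror symmetry
    and quantifies residual asymmetry, classifies side shapes against a
    reference-outline library by correlation, computes calibrated widths,
    heights and top-view circle metrics, and builds per-fruit hue and
    saturation histograms. Per-fruit records are aggregated into per-cultivar
    summaries with ANOVA and Tukey significance letters, k-means shape
    clusters and one-page factsheets. A quantile-based resampling procedure
    estimates the relative margin of error of trait means as a function of
    sample size to recommend a minimal number of fruit per accession. A
    synthetic five-view fruit renderer with known ground truth supports
    testing and simulation without any camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    ggplot2,
    patchwork,
    stats,
    grDevices,
    utils,
    grid
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
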