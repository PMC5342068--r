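Package: ihcquant
Title: Color-Based Segmentation and Quantification of IHC Brightfield Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying immunohistochemistry
    (IHC) brightfield images by color-based segmentation: RGB images are
    converted to CIELAB, pixels are clustered by k-means on the (a*, b*)
    chromaticity plane, and marker-positive area is measured after
    size-based morphological filtering. Supports cytoplasmic DAB markers,
    nuclear markers via two-tier (k=3 then k=2) clustering into six
    non-overlapping sub-masks, tumor-area estimation, and positive-nucleus
    counting. Includes cohort-level statistics (patient averaging, Spearman
    correlation, mean-based dichotomization into a 2x2 contingency table,
    rank-sum tests), protein half-life estimation from translation-block
    densitometry time courses, caliper-based xenograft tumor volume, and
    synthetic-data generators (IHC-like images with exact ground truth,
    correlated patient cohorts, exponential decay series) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    farver,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
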