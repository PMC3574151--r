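Package: cfuCounter
Title: Robust Counting of Cell Colonies and Other Circular Objects in Plate Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and counts colony-forming units (CFU) and other bright or
    dark circular objects in digital pictures of agar plates. A contrast-enhanced
    grey-scale image is scanned over many binarisation thresholds; connected
    components that are recurrently classified as circular by a morphological
    particle filter vote into a per-pixel score map, which is thresholded and
    segmented. Merged colonies are split with a chamfer distance transform and a
    marker-constrained watershed, and an optional colour filter excludes outlier
    objects. Includes automatic Petri-dish detection by Hough circle transform,
    batch processing with summary and per-colony output tables, and a synthetic
    plate-image generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation
RoxygenNote: 7.3.3
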