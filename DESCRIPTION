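Package: fiberseg
Title: Watershed Segmentation and Morphometry of Immunofluorescent Muscle Histology
Version: 0.1.0
Authors@R: person("fiberseg", "developers", role = c("aut", "cre"),
    email = "fiberseg@example.org")
Description: Scriptable pipeline for quantitative histology of skeletal muscle
    cross-sections stained by immunofluorescence. Segments fibers from a
    membrane-outline channel (e.g. laminin) by suppression of shallow local
    minima followed by the watershed transform, filters non-fiber objects by
    edge contact, area, eccentricity and convexity, and reports per-fiber
    morphometry (cross-sectional area, minimum and maximum Feret diameter,
    Feret direction), fiber-type calls from mean stain intensity with an
    Otsu-initialised threshold, centrally nucleated fiber detection from a
    nuclear channel using an exact Euclidean border distance, and counts of
    extra-fiber objects such as capillaries. Interactive editing steps are
    replaced by file-driven inputs (separation polylines, removal lists), and
    a ground-truthed synthetic section generator makes every stage testable
    without slide images. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jpeg,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    zip
Config/testthat/edition: 3
RoxygenNote: 7.3.3
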