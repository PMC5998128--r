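Package: cyanocount
Title: Automated Enumeration of Cyanobacteria from Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-phase image-analysis pipeline for identifying,
    differentiating, and enumerating cyanobacterial and algal cells in
    single-channel fluorescence micrographs. Pixel-level foreground
    classification by between-class-variance (Otsu) threshold learning,
    connected-component analysis, extraction of seven morphological
    descriptors (area, perimeter, eccentricity, compactness, convex area,
    solidity, extent), rule-cascade and quadratic-kernel support-vector
    classification of components, unit-cell projected-area calibration,
    and conversion of per-image counts to cell concentrations for
    hemocytometer-mounted samples. Includes a ground-truthed synthetic
    micrograph generator emulating unicellular, filamentous, and
    spindle-shaped taxa for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
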