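Package: ichmorph
Title: Automated Morphometry of Flow-Through Imaged Fish Eggs and Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for millimetre-scale ichthyoplankton imaged
    in a back-lit flow-through system. Selects candidate frames from an image
    stream by moving-average background subtraction and blob filtering,
    enforces rule-based validity conditions on instance segmentation masks
    produced by an external segmenter, and extracts biologically relevant
    morphometrics: standard length from a pruned skeleton centerline, facing
    direction, second-moment major and minor axes, projected areas, and
    closed-form volume estimates (cylindrical larva body, prolate-spheroid
    yolk sac and eye, spherical egg). A synthetic scene and stream generator
    with exact ground truth supports end-to-end validation without camera
    data or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
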