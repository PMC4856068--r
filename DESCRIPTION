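Package: bacumorph
Title: Landmark-Free 3D Morphometrics and QTL Mapping of Baculum Size and Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A landmark-free geometric-morphometric pipeline for elongate bones
    imaged by micro-CT, built around the mouse baculum. Segments bones from
    voxel stacks, places each point cloud in a canonical frame (proximal end at
    the origin, long axis on +z, minimum-bounding-rectangle long side on x),
    extracts 802 rule-based semilandmarks per bone, and quantifies size
    (centroid size) and shape (generalized Procrustes superimposition with
    sliding semilandmarks, pairwise Procrustes distances, and a parental-strain
    linear discriminant axis). A quantitative-genetics layer provides
    repeatability, nested environmental ANOVA, ANOVA heritability, and
    single-QTL genome scans for recombinant inbred panels by Haley-Knott
    regression with permutation significance thresholds and 1.5-LOD support
    intervals. Synthetic bone phantoms and simulated RIL panels make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
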