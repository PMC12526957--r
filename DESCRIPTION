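Package: rhizoshape
Title: Multiangle Root-System Architecture Phenotyping from 2D Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments plant root systems from turntable image series,
    thins the mask to a centerline graph, and extracts a registry of 16
    macrophenotype and 96 layered microphenotype shape descriptors
    (convex hull, stratified area profiles, ellipse-ladder coverage,
    scan-line crossing counts, skeleton length, tips, diameter,
    directionality). Per-view trait vectors are aggregated across
    replicates and rotation angles into accession-level tables ready for
    association mapping, with Pearson trait correlation and a 1/n
    suggestive significance threshold. Includes a stochastic 3D
    root-growth simulator with orthographic multi-view rendering that
    supplies the training library for the random-forest pixel segmenter
    and exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    png,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
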