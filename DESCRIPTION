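Package: vineseg
Title: Sequential Multispectral Masking for Vineyard Scene Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-level discrimination of grapevine canopy elements from
    co-registered RGB and narrow-band (635 nm, 660 nm, 880 nm) imagery. A
    sequential masking classifier built on seeded K-means peels off
    background, fruit, stems and finally leaves versus branches, each stage
    clustering the band in which the remaining classes contrast most. The
    package also provides an RGB-only five-cluster baseline, per-class
    evaluation (hit rate, false-positive rate, precision, accuracy, ROC
    points, cross-scene aggregation), and a seeded synthetic vineyard scene
    generator with ground truth so the whole system is testable without
    field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    farver,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
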