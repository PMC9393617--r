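Package: shootpheno
Title: Marker-Plate Calibration and Architecture Traits from 3D Plant Shoot Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Processes colored point clouds of potted plant shoots reconstructed by
    multi-view stereo. A red circular marker plate of known diameter is segmented in
    HSL color space and its circumcircle fitted to recover the unknown reconstruction
    scale; the scene is restored to real-world units with an upright frame, the shoot
    is isolated by cylinder cropping, ground and pot removal, random down-sampling and
    statistical denoising, and architecture traits are extracted: plant height,
    projected area, multi-layer projected area, mesh-based leaf area, convex hull
    volume and compactness. A ground-truthed synthetic scene generator makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    interp,
    jsonlite,
    purrr,
    RANN,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
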