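Package: polypscene
Title: Stable Polyp-Scene Classification for Colonoscopy Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatiotemporal classification of colonoscopy video into polyp and
    non-polyp scenes. Extracts overlapping 16-frame chunks from annotated
    videos, trains 3D residual convolutional networks with either balanced
    class weighting or an epoch-wise 1:1 negative-subsampling scheme that
    always retains hard-negative chunks, applies temporal post-processing
    that keeps only runs of at least N consecutive above-threshold chunks,
    and evaluates at chunk level (sensitivity/specificity over a threshold
    grid) and at scene level (detection accuracy and false-positive scene
    duration). Includes a seeded synthetic colonoscopy-like video generator
    so the full pipeline is testable without clinical data, and a compact
    CPU 3D convolutional network engine (im2col + BLAS) used by the models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
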