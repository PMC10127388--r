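Package: rapecount
Title: Density-Map Counting of Rapeseed Flower Clusters in Aerial Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Counts rapeseed (Brassica napus) flower clusters in plot-scale
    RGB imagery by density-map regression. Provides a lightweight pyramidal
    convolution network (with an optional coordinate-attention variant)
    trained under a Bayesian point-supervision loss that needs only one
    annotated centroid per cluster, together with annotation readers for
    rectangular-box (Pascal VOC XML) and centroid (CSV/JSON) labels, tiled
    inference over standard 512x1024 plot canvases, count-accuracy metrics
    (Acc, MAE, rMAE, rMSE, rrMSE, R2), heat-map rendering, and a seeded
    synthetic field-scene generator so every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    farver,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
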