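Package: celltrax
Title: Spatial and Behavioural Analysis of Segmented Multiplexed Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative spatial analysis of segmented multiplexed 2D/3D
    microscopy images and semi-supervised behaviour classification of tracked
    cells. Covers neighbour graphs (Delaunay, radius, k-nearest), density-based
    aggregate detection, cellular-neighbourhood regions by K-means, distances
    to tissue structures, cell-cell contacts, hierarchical histo-cytometry
    gating, per-track motility statistics, Gaussian hidden Markov behaviour
    states with Viterbi decoding, fusion of track statistics with state
    occupancies and transitions into behaviour clusters via Leiden community
    detection, collective-motion flow fields with a nematic anisotropy score,
    and ground-truthed simulators for tracks, tissue layouts and label images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
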