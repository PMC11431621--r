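Package: misep
Title: Time-Separated Mutual Information for Leader-Follower Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to probe asymmetric, time-delayed interactions in animal
    dyads using the mutual information between one individual's position now
    and the other's position a time separation tau earlier. Provides a ring
    leader-follower simulator with stochastic leadership swaps, a
    Kraskov-Stogbauer-Grassberger k-nearest-neighbour mutual information
    estimator, decorrelated single-trajectory sampling via symmetric
    triangular windows, preprocessing of top-view tank trajectories (polar
    transform, heading repair, alignment angles, drift/noise estimation),
    synthetic tracking-style data rendering, and LOESS-based peak
    localisation to extract the follower's reaction timescale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
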