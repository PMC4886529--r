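Package: ringmig
Title: Quantitative Analysis of Single-Cell Migration in Ring-Shaped Microlanes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify single-cell migration on ring-shaped
    micropatterned lanes. Trajectories of nucleus centroids are projected to
    polar coordinates, the tangential velocity series is segmented into
    directionally persistent run states and localized rest states by an
    iterative change-point analysis based on cumulative-sum (CUSUM)
    statistics with mean-squared-displacement classification, and the state
    persistence times and run velocity are estimated from exponential tails
    of dwell-time survival functions. Interactions with non-adhesive
    (PEGylated) barriers are quantified through turning probabilities with
    exact binomial confidence intervals, an exponential transit-decay
    length, and the invasion-depth survival law. The five-parameter
    migratory fingerprint can be rendered as a radar chart. A two-state
    trajectory simulator with exponential dwell times provides ground truth
    for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
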