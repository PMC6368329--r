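Package: nanocluscol
Title: Nanoscale Cluster and Colocalization Analysis for Two-Channel
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-channel single-molecule localization
    microscopy (SMLM/dSTORM) coordinate data. Implements coordinate-based
    degree-of-colocalization (DoC) scoring, DBSCAN cluster detection with
    interaction-class assignment (no/low/high interaction clusters),
    convex-hull cluster morphometrics, and an unbiased variable-bandwidth
    mean-shift (VBMS) cluster analysis with DBSCAN pre-partitioning and
    truncated kernels. Includes a synthetic scene simulator (complete
    spatial randomness, Thomas cluster processes, fluorophore blinking,
    localization error) that provides ground truth for validating every
    stage of the pipeline, point-weighted histograms, group statistics,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
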