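Package: nichecast
Title: Penalized Maximum-Entropy Species Distribution Modelling and
    Climate-Change Range Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presence/background species distribution modelling
    with a from-scratch L1-penalized maximum-entropy (Maxent-family) model
    supporting linear, quadratic, hinge, product and threshold features,
    regularization-multiplier and feature-class tuning by small-sample
    corrected AIC (AICc) with AUC and 10 percent omission diagnostics,
    projection to altered climate layers, suitability classification with
    fixed bands or Jenks natural breaks, spherical area accounting, range
    expansion/contraction change matrices, multivariate environmental
    similarity surfaces (MESS) with most-dissimilar-variable grids, and
    suitable-habitat centroid migration. Includes a synthetic-scenario
    generator (spatially autocorrelated layers, log-linear species density,
    additive climate shifts) so the full pipeline runs without external
    raster downloads, and a staged pipeline driver with a command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
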