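Package: arsnpmr
Title: Nonparametric Multiplicative Regression for Area-Restricted-Search
    Habitat Analysis of Satellite-Tracked Whales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links satellite-tracked whale behavioral state (area-restricted
    search versus transiting) to oceanographic predictors with nonparametric
    multiplicative regression (NPMR): local-mean Gaussian-kernel estimation
    with leave-one-out cross-validation, free stepwise model search with
    tolerance tuning, bootstrap and randomization inference, binary
    classification assessment at the TSS-maximizing cutoff, and empirical
    variogram diagnostics of spatial autocorrelation. Includes track
    filtering rules for state-space-modeled daily locations, credible-box
    kernel-weighted extraction of gridded environmental fields, latitudinal
    loess detrending, a collinearity screen, a two-state movement simulator
    with matched environmental fields for end-to-end validation, and a
    configurable pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
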