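Package: lurf
Title: Parsimonious Random-Forest Land-Use Regression for Mobile PM2.5 Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds land-use regression models for fine particulate matter
    (PM2.5) from mobile low-cost sensor transects. Covers the full workflow:
    kappa-Koehler humidity correction of optical particle counter readings,
    percentile trimming, temporal-median smoothing and background subtraction;
    aggregation of repeated rounds onto an idealised route; multi-radius buffer
    statistics over gridded land-use predictor layers; Monte-Carlo random-forest
    ensembles; feature screening by recursive feature elimination (with and
    without cross-validation) and by variance-based Sobol' global sensitivity
    analysis with Saltelli sampling; and hold-out plus reference-station style
    validation. A seedable synthetic-scene generator emulates bicycle campaigns
    over known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
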