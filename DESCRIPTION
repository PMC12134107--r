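Package: drykin
Title: Thin-Layer Drying Kinetics, Diffusivity and Quality Analysis for
    Infrared-Convective Drying
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for infrared-convective thin-layer drying
    experiments on sliced vegetables. Fits the eleven classical
    semi-empirical thin-layer models (Newton, Page, Midilli-Kucuk, ...)
    to moisture-ratio curves by multi-start Levenberg-Marquardt least
    squares and ranks them by the R2 / chi-square / RMSE rule; estimates
    effective moisture diffusivity by the Fick slab slope method and
    activation energy by Arrhenius regression; computes physicochemical
    quality indices (CIELAB colour change, browning index, shrinkage and
    rehydration ratios, vitamin C retention, water-activity screening);
    fits linear and quadratic response-surface correlations of process
    variables; and trains a from-scratch feed-forward neural-network
    surrogate and Kohonen self-organizing map over drying conditions.
    Includes a seeded synthetic drying-experiment generator so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
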