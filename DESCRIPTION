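Package: searchits
Title: Segmented Log-Normal Mixed Models for Daily Search-Index Panels
Version: 0.1.0
Authors@R:
    person("Search-ITS", "Developers", email = "searchits@example.org",
           role = c("aut", "cre"))
Description: Interrupted time-series analysis of provincial daily
    search-index panels using segmented log-normal linear mixed models
    with province-level random intercepts and slopes and first-order
    autoregressive (AR(1)) residual correlation. Provides a synthetic
    panel generator with known ground truth, design-matrix construction
    for step/slope exposure segments interacted with socioeconomic
    strata (Human Development Index categories or standardized
    continuous covariates), a maximum-likelihood fitter with profiled
    generalized least squares, effect summaries as rate ratios and
    ratio-of-rate-ratio contrasts with Holm-Bonferroni adjustment,
    descriptive median/IQR tables, and an end-to-end reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
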