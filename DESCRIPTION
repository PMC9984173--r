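Package: crisiscast
Title: News-Based Early Warning of Food Crises
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning district-tagged news streams into early-warning
    forecasts of food-insecurity (IPC) phases. Implements causal text-feature
    extraction from frame-semantic parses, word mover's distance keyword
    expansion, construction of monthly news-factor panels at district,
    province and country level, panel Granger-causality screening with
    ADF-guided differencing, lagged random-forest phase forecasting under
    temporal cross-validation, and food-crisis outbreak classification with
    dual-threshold precision-recall sweeps and Diebold-Mariano forecast
    comparison. A fully synthetic scenario generator (geography, latent risk,
    IPC phases, traditional risk factors, embeddings, articles and semantic
    frames) makes every stage testable without access to proprietary news or
    assessment data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
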