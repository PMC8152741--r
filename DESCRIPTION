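Package: geoassay
Title: Error Geography of Trace-Metal Soil Assay Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the geography of analytical assay
    measurement error in urban soil trace-metal surveys. Fits
    three-parameter log-normal error models by order-statistics (rankit)
    regression with goodness-of-fit diagnostics, simulates measurement,
    sampling (tract-stratified bootstrap) and specification (gamma, beta,
    uniform) error sources, quantifies the stability of varimax-rotated
    error dimensions across simulation replications, computes Moran and
    Geary spatial autocorrelation indices and simultaneous autoregressive
    (SAR) variance inflation, and builds uncertainty-aware choropleth
    class breaks by a separability criterion. A synthetic survey
    generator reproduces the statistical structure of a multi-metal
    point-sample survey over a tract tessellation so that every stage is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
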