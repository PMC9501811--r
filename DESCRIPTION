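Package: uelshift
Title: Climatic Equilibrium of Species' Upper Elevational Range Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a species' observed upper elevational limit (UEL)
    on a mountain gradient is in equilibrium with its global climatic niche.
    The niche is delineated as the densest 99% of an occurrence kernel density
    in a gridded two-axis PCA environmental space calibrated on global
    background climates; regional points are classified climatically suitable
    or unsuitable by intersection with the niche; Huisman-Olff-Fresco (HOF)
    response curves fitted to the resulting presence/absence series along
    elevation yield a predicted UEL as the exp(-2) outer border, with a 95%
    confidence interval from repeated stratified 25% subsampling. Includes a
    synthetic-data generator with analytically known true limits, the
    comparative statistics for temporal limit change and observed-vs-predicted
    regression, and ggplot2 graphics for each result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
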