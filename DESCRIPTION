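Package: hotgrid
Title: Spatial Hotspot Detection and Evaluation on Gridded Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and evaluates spatial hotspots in gridded count data
    (crime incidents, disease cases, accidents) using four statistics-based
    detectors: the Poisson circular spatial scan statistic, the Getis-Ord G*
    local statistic, local Moran's I, and AMOEBA ecotope region growing.
    Includes a quantitative evaluation framework with concentration
    indicators (hit rate, area ratio, prediction accuracy index, density
    contrast ratio), a standardized shape index for patch complexity, and
    confusion-matrix accuracy measures against a ground-truth mask.  A
    synthetic scenario generator plants irregularly shaped hotspots with
    upper-tail Poisson counts on a noise background so detector performance
    can be benchmarked with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
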