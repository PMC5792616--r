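Package: landgea
Title: Multiscale Landscape Genomics with Terrain-Derived Environmental Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fine-scale landscape genomics with dominant
    (presence/absence) markers along topographically complex terrain. Builds a
    multiscale raster pyramid from a very high resolution digital elevation
    model by cubic B-spline smoothing, derives geomorphometric habitat proxies
    (slope, aspect components, ruggedness, topographic openness, sky-view
    factor, wetness index, flow path length, wind exposure, clear-sky solar
    radiation), infers admixture structure by fuzzy c-means clustering with
    greedy label alignment, quantifies spatial genetic autocorrelation in
    balanced distance classes with permutation tests, and scans for
    gene-environment associations with binomial mixed models using raster
    pixels as random intercepts across spatial resolutions. Includes a
    synthetic ridge-landscape generator so every stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    e1071,
    vegan,
    yaml,
    ggplot2
Config/testthat/edition: 3
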