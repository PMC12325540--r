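Package: tdaniche
Title: Topological Classification of Tumour-Immune Spatial Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vectorises time series of tumour, macrophage and blood-vessel
    coordinates with four topological summaries - persistence images of
    Vietoris-Rips and radial filtrations at single timesteps, and of
    persistence vineyards and zigzag filtrations over time windows - and
    trains cross-validated logistic regression to predict the formation of
    perivascular tumour niches. Includes a self-contained agent-based
    caricature of tumour-macrophage dynamics that generates labelled
    synthetic cohorts in three qualitative regimes (equilibrium,
    elimination, escape), persistence engines for dimensions 0 and 1
    (union-find and mod-2 boundary reduction) and an interval-decomposition
    algorithm for dimension-0 zigzag persistence over intersection
    complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
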