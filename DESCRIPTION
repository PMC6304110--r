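Package: nichepack
Title: Species Packing in Morphospace and Isotopic Niche Metrics for
    Community Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing the structure of animal communities
    (developed for bat assemblages) along two complementary axes: an
    ecomorphological morphospace built from size-corrected linear
    measurements, and the bivariate stable-isotope (d13C, d15N) niche
    space. Implements allometric size correction by regression on body
    mass, per-community principal component morphospaces, species-packing
    metrics (nearest-neighbour and centroid distances, minimum convex
    polygon area), richness-controlled rarefied bootstrap comparisons
    with rank-sum tests, the six Layman community isotope metrics,
    standard ellipse areas (SEA, SEAc) with Bayesian credible intervals
    from a conjugate normal-inverse-Wishart posterior, and a synthetic
    two-community generator for testing every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
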