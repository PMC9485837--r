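Package: silenemorph
Title: Floral Trait Convergence Analysis for North American Silene
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of floral-trait convergence in North American
    Silene (Caryophyllaceae): trait-table coding and summary statistics,
    phylogenetic signal (Pagel's lambda, Blomberg's K), phylogenetic ANOVA with
    a Brownian-motion simulation null, Mk models of discrete floral-color
    evolution with AIC model selection, marginal ancestral-state reconstruction
    and stochastic character mapping, phylogenetic PCA morphospace with
    permutation tests of group variance ratios and mean differences, uniform
    trait-range resampling robustness checks, and occurrence-derived species
    range overlap with sympatry classification and disparity-by-geography
    statistics. Includes a synthetic-data generator with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    graphics,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools
Config/testthat/edition: 3
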