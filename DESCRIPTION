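Package: fitpaths
Title: Predictability of Evolution on Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("fitpaths", "developers", email = "fitpaths@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the predictability of adaptive evolution on
    genotype-fitness landscapes over binary loci. Enumerates fitness-monotonic
    mutational paths under strong-selection/weak-mutation (SSWM) dynamics,
    computes their occurrence probabilities, inter-path distances and the
    ensemble/mean path divergence statistic, peak accessibility, and four
    landscape-roughness measures, together with a noisy-additive landscape
    generator, an uncorrelated (house-of-cards) null, and fitness-permutation
    null comparisons. Landscapes are read and written as plain-text
    genotype-fitness tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
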