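Package: cavecharr
Title: Genetic and Phenotypic Divergence in Small Fragmented Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing neutral genetic and phenotypic divergence
    among small, recently fragmented populations, motivated by groundwater
    cave populations of Arctic charr (Salvelinus alpinus). Provides
    microsatellite diversity and differentiation statistics (Weir-Cockerham
    theta, Jost's Dest, Cavalli-Sforza and Edwards chord distance, rarefied
    allelic and private-allelic richness, exact-style Hardy-Weinberg and
    allele-frequency heterogeneity tests), neighbour-joining phenograms with
    bootstrap consensus, Mantel and partial Mantel isolation-by-distance
    tests, landmark-based geometric morphometrics (generalized Procrustes
    analysis with sliding semilandmarks, shape PCA, permutation Procrustes
    linear models, discriminant classification, mean-shape disparity),
    Lincoln-Petersen/Chapman mark-recapture census estimation, and a
    restricted-maximum-likelihood mixed model that partitions among-population
    phenotypic variance into environment-associated, genetic-structure-
    associated and residual components. A synthetic-data module generates
    genotypes, environments, phenotypes, landmark configurations and capture
    histories with known ground truth so every stage of the pipeline can be
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    MASS,
    geosphere,
    stats,
    utils
Suggests:
    lme4,
    vegan,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
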