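Package: phenodiv
Title: Phenotypic Genetic Divergence Analysis for Plant Diaspore Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative-genetics analysis of replicate-level phenotype
    tables from completely randomized designs, as used to characterize
    genetic divergence among tree genotypes from fruit and seed (diaspore)
    traits. Provides per-trait one-way ANOVA with broad-sense heritability,
    genetic and environmental coefficients of variation, Scott-Knott
    grouping of genotype means, generalized Mahalanobis D2 and standardized
    mean Euclidean distance matrices, Tocher optimization clustering, UPGMA
    dendrograms with Mojena cutoff and Newick export, Singh's relative
    trait-importance decomposition, canonical variate analysis, Pearson
    correlation matrices, seedling-emergence indices (emergence percentage,
    Maguire's emergence speed index, Edmond-Drapalla mean emergence time),
    and a synthetic-data generator with known heritabilities and genetic
    correlations for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
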