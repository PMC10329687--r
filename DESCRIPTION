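Package: geophylo
Title: Geographic Clustering of Within-Species Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how much of a bacterial species' gene-tree variation
    is explained by the geographic region of sampling. Implements PERMANOVA
    (Gower-centered trace formulation with a seeded permutation null) on
    patristic distance matrices, city-level tip deduplication and
    single-region-tip filtering, stratification of genes into membrane,
    organelle and metabolic groups from top-level cellular-component labels,
    Kruskal-Wallis and pairwise Wilcoxon group contrasts with
    Benjamini-Hochberg correction, covariate bias diagnostics, Nei-Gojobori
    (1986) per-gene dN/dS with bacterial framing rules, genome-abundance
    normalization (expected coverage, rarefaction, TPM, Shannon diversity),
    and an island-model structured-coalescent simulator that generates
    region-structured datasets with known selection truth for end-to-end
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
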