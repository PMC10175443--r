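Package: microvar
Title: Partitioning Technical and Biological Variation in Microbiome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of nested technical-replicate microbiome
    study designs comparing 16S amplicon-like and shallow shotgun-like
    measurements of the same communities. Provides a hierarchical
    compositional community simulator with independent variance components
    for subject, week, day, DNA extraction and library preparation; a
    shotgun read-profiler implementing capitalist (minimum-unique-OTU)
    tie-breaking, lowest-common-ancestor taxonomic assignment,
    genome-length normalization and abundance/coverage/depth filtering;
    rarefaction, alpha diversity and Bray-Curtis/PCoA beta diversity;
    partitioning of pairwise dissimilarities into library-prep, extraction,
    daily, weekly and between-subject variation sources; and the associated
    statistical tests (PERMANOVA, multivariate dispersion homogeneity,
    Kruskal-Wallis with Dunn's post-hoc and Benjamini-Hochberg correction,
    two-way ANOVA, pooled t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    withr
Config/testthat/edition: 3
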