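Package: bifpopgen
Title: Population Genomics, Transmission and Host-Association Analysis for
    Gut Bifidobacterium Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Core-genome SNP calling from reference-coordinate genome
    alignments, pairwise SNP distances and neighbor-joining phylogenies,
    iterative clonal pruning, simplified chromosome painting into a
    co-ancestry matrix with hierarchical population clustering and palettes,
    haploid Weir-Cockerham fixation index, one-vs-rest population GWAS with
    COG/KEGG enrichment, MinHash (Mash-type) sketch distances with classical
    MDS structure correction for fixed-effect phenotype GWAS,
    semi-clonal/clonal group transmission inference with windowed
    recombination masking, and community statistics (Hellinger transform,
    tb-RDA, PERMANOVA, rank tests with compact letter displays). Includes a
    synthetic cohort generator that plants population structure, clonal
    expansions, recombination imports, phenotype-associated variants and
    covariate-driven abundance tables so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
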