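Package: pedmapr
Title: Allele-Balance Identity-by-Descent Mapping and Variant
    Prioritization in Small Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps disease loci in small sequenced families by
    allele-balance identity-by-descent (IBD) analysis of a multi-sample
    VCF: per-sample hard filters on depth and genotype quality, Mendelian
    consistency checks in pedigree trios, a pairwise allelic-ratio
    difference statistic, run-based segmentation into IBD segments, and
    intersection of segments across all affected pairs under a dominant
    model. Downstream, shared regions are intersected with external gene
    prioritization scores, multi-caller structural-variant call sets are
    merged by reciprocal overlap and breakend distance and filtered by
    inheritance and phenotype-gene overlap, and dual-luciferase reporter
    assays are analysed with an exact Mann-Whitney U test and a Z-based
    effect size. A seeded gene-dropping simulator generates pedigree
    genotypes, SV call sets and assay measurements with known truth so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
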