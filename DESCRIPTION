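Package: famburden
Title: Familial Rare-Variant Collapsing Burden Analysis with Pedigree
    Segregation and Gene-Set Enrichment
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering disease genes from rare disruptive
    variants in familial case-control sequencing studies. Implements
    genotype- and site-level variant quality control (genotype quality,
    heterozygous allele-balance chi-square, Hardy-Weinberg exact test,
    call rate, alignability and repeat masking), selection of rare
    disruptive qualifying variants per gene, a pedigree-aware T1
    collapsing carrier burden test with permutation significance and
    frequency-ratio odds ratios, within-family segregation filtering,
    pre-ranked gene-set enrichment with a gene-permutation null and
    Benjamini-Hochberg Q values, Fisher-exact replication against
    external control carrier counts, and a Monte-Carlo power calculation
    over allele-frequency by relative-risk grids. A synthetic cohort
    generator emulating familial pedigrees, sporadic cases, controls and
    genotype-level noise makes the whole pipeline testable end to end
    without access to protected germline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
biocViews: GeneticVariability, VariantAnnotation, GeneSetEnrichment,
    StatisticalMethod, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
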