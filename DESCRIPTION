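Package: radpop
Title: RADseq Population Genomics: Diversity, Differentiation and
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for restriction site-associated DNA (RAD) marker design
    and population-genomic analysis of wild tomato collections and similar
    diversity panels. Performs in-silico restriction digestion and
    sequencing-unit construction, genotype-matrix filtering (call-rate,
    minor allele frequency, within-unit redundancy pruning by complete
    linkage disequilibrium), diversity and differentiation statistics
    (observed heterozygosity, Nei-Chesser gene diversity, Weir-Cockerham
    Fst, distance-based AMOVA with permutation tests, PCA, Mantel
    isolation-by-distance), and linkage-disequilibrium analysis from
    unphased genotypes (EM haplotype-frequency r-squared, Hill-Weir decay
    fitting, local LD profiles over consecutive sequencing units). A
    seeded synthetic-data generator produces structured and admixed
    genotypes, distance-decaying LD, and toy genome fixtures so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    geosphere,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
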