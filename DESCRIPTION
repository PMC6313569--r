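Package: trioscan
Title: Trio Whole-Genome Variant Prioritization and Dioxin TEQ Arithmetic
Version: 0.1.0
Authors@R:
    person("trioscan", "developers", email = "trioscan@example.org",
           role = c("aut", "cre"))
Description: Family-trio (father, mother, proband) whole-genome variant
    prioritization: de novo SNV/indel candidate detection by dual
    parent-proband comparison with an edge-of-read indel artifact filter,
    recessive-model filtering (compound heterozygosity with parental-origin
    assignment, homozygous-recessive calls, population allele-frequency
    exclusion), depth-of-coverage copy-number segmentation by an in-house
    circular binary segmentation implementation with trio copy-state
    classification, mutation-spectrum statistics (transition/transversion
    ratio, CpG-context proportion, per-generation rate), and WHO toxic
    equivalency (TEQ/TEF) arithmetic for dioxin congener panels. Includes a
    seeded synthetic trio-data generator that emits Mendelian-consistent
    reference, gene-model, VCF and depth files with a machine-readable truth
    table, so every pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
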