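Package: isomiRQTL
Title: IsomiR Identification, Classification and cis-SNP Association from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies microRNA sequence isoforms (isomiRs) from small-RNA
    sequencing reads by multi-round alignment to hairpin precursor references
    (perfect match, genome filtering, one-mismatch, and iterative end-trimming
    rounds that expose non-templated terminal bases), classifies 5'/3'
    variation into the standard isomiR taxonomy, removes reference-allele
    alignment bias with personalized (alternative-allele) references, and
    tests cis-acting SNPs for association with 5'-isomiR composition ratios
    using Kendall rank correlation with population-stratified
    Benjamini-Hochberg control. A fully specified synthetic-cohort generator
    (references, annotations, genotypes, reads, ground truth) makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
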