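Package: lsblscan
Title: Breed-Specific Selection-Signature Scans with Locus-Specific
    Branch Lengths and the d Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic regions under breed-specific selection in
    SNP-chip panels of three or more populations. Computes per-locus
    pairwise Weir-Cockerham F_ST, combines the pairwise values into
    locus-specific branch lengths (LSBL) and the standardized d
    statistic for each breed, aggregates per-SNP scores into 300-kb
    windows, flags windows in the empirical upper tail of each
    statistic, and intersects the two statistics' candidate lists.
    Includes quality-control filtering (minor allele frequency,
    Hardy-Weinberg exact test, autosome restriction), sliding-window
    LD pruning, principal component analysis, a three-branch F_ST
    phylogeny, gene-interval annotation of candidate windows, and a
    Balding-Nichols genotype simulator with planted selective sweeps
    for power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    vcfR,
    jsonlite,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
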