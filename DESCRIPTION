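Package: asepipe
Title: Allele-Specific Expression Analysis in F1 Hybrids via a
    Pseudo-Reference and Read-Wise Allele Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) in an F1 hybrid
    from RNA-seq of the hybrid and its two inbred parents.  Builds a
    consensus pseudo-reference transcriptome by editing in variants shared
    by both parents, assigns hybrid reads to parental alleles read-wise at
    inter-parental SNPs, tests each gene for allelic imbalance with exact
    binomial and chi-square tests after median-of-ratios normalization,
    classifies condition-mediated ASE profiles (presence/absence variation,
    bidirectional and unidirectional allele preference) between a control
    and a stress treatment, and associates imbalanced genes with trait
    markers by physical co-localization and selective-genotyping single
    marker regression.  A seeded simulator generates reference, parental
    haplotypes, reads and a recombinant-inbred-line panel with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
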