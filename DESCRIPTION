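Package: pgdecko
Title: Paired-Guide CRISPR Deletion Screen Design and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis pipeline for pooled paired-guide (pgRNA)
    CRISPR-Cas9 deletion screens read out by FACS sorting and amplicon
    sequencing. Covers nomination of candidate genes from two-replicate
    time-course FPKM matrices (expression and fold-change filters, lncRNA
    TSS isolation, k-means profile clustering), design of ranked paired-gRNA
    constructs against coding ORFs and lncRNA transcription start sites
    (protospacer enumeration, on-target scoring hook, Hamming off-target
    filtering, 165-nt cloning-oligo emission, positive and intergenic
    controls), anchor-based guide-pair quantification from paired FASTQ
    against a 41-bp artificial reference, and candidate calling via the
    differentiation-delaying effect (DDE) statistic with decile thresholds
    and replicate consistency. A synthetic-data module generates every
    input (toy genome and annotation, noisy expression time courses,
    screen reads with planted effects) so the full pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
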