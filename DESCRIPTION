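Package: lncflow
Title: Long Noncoding RNA Discovery and lncRNA-mRNA Integration Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies long noncoding RNAs (lncRNAs) from assembled
    transcripts by removing known mRNAs and short (<200 nt) fragments,
    scoring protein-coding potential with an open-reading-frame plus
    Fickett TESTCODE composite, and classifying survivors by genomic
    position (exonic sense overlap, antisense, intronic, intergenic).
    Quantifies expression as FPKM, calls differential expression between
    two groups with a fold-change plus Benjamini-Hochberg FDR rule,
    predicts cis-target genes within a 100 kb genomic window, scans
    differentially expressed lncRNAs for microRNA-precursor homology by
    Smith-Waterman local alignment, performs hypergeometric gene-set
    enrichment, and assembles concordant-trend lncRNA-mRNA core networks.
    Ships a seeded synthetic-data generator with planted ground truth so
    the whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    Rcpp,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
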