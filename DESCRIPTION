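Package: ribotrans
Title: Transcriptome and Translatome Analysis for Bacterial Ribosome
    Profiling and dRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level analysis of condition-paired bacterial RNA-Seq,
    ribosome profiling (Ribo-Seq) and differential RNA-Seq (dRNA-Seq)
    5'-end data. Implements RPKM quantification with initiation/termination
    codon exclusion, median-of-ratios normalization, simple differential
    expression calls, translation-efficiency (TE) classification with a
    Gaussian one-standard-deviation fold-change threshold, translational
    buffering and gene-set enrichment statistics, transcription start site
    (TSS) calling from RPP+/RPP- library pairs with primary/secondary/
    internal/antisense categorization and 5'-UTR assignment, metagene and
    reading-frame periodicity profiles, 5'-UTR ribosome occupancy, a
    Nussinov base-pair maximization folding engine with a pluggable
    thermodynamic backend, Shine-Dalgarno scoring, and operon/complex
    subunit stoichiometry diagnostics. Includes a synthetic-data generator
    that emulates the structure of such experiments with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
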