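Package: zygosnp
Title: Detecting Zygotic Transcription from Allele-Specific RNA-Seq in
    Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting zygotic transcription in pre-blastoderm
    embryos from F1-hybrid RNA-seq. Reads overlapping single-nucleotide
    polymorphisms that distinguish the two parental lines are assigned to
    the maternal or paternal chromosome, tabulated per gene and
    developmental stage, RPKM-normalized on autosomal genes, and
    classified as maternally deposited or zygotically transcribed with an
    exact binomial test against the sequencing-error ceiling. A
    synthetic-data module simulates diploid transcriptomes, stage-
    structured maternal/zygotic expression programs, error-bearing short
    reads, and Mendelian crosses, so the whole pipeline is testable
    against known ground truth. Feasibility arithmetic for transcription
    and translation within short syncytial interphases is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
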