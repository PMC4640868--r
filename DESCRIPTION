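Package: DirectTargets
Title: Integrative Nomination of Direct Transcription-Factor Targets from
    Knockdown Transcriptomes, ChIP-seq Cistromes and Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to nominate direct transcriptional targets of an
    amplified transcription factor by intersecting three evidence layers:
    knockdown response classification from RNA-seq expression tables
    (ratio thresholds on well-measured genes), ChIP-seq peak-to-gene
    annotation within a genomic window of transcription start sites
    (with IUPAC consensus motif scanning of peak windows), and a
    copy-number-stratified tumor cohort comparison using a two-class
    SAM permutation statistic. Includes a weighted running-sum gene-set
    enrichment analysis (GSEA) with phenotype permutation, a
    hypergeometric gene-set overlap utility, and a seeded synthetic-data
    generator with planted ground truth so the whole pipeline can be
    exercised and validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    rtracklayer,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
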