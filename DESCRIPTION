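Package: methdyn
Title: Tissue-Specific and Developmental DNA Methylation Dynamics from
    Methylation Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for calling tissue-specific hypomethylation
    signatures and developmental gain/loss-of-methylation (GOM/LOM)
    trajectories from normalized beta-value matrices of Illumina
    450k-style methylation arrays. Includes threshold-based probe
    calling across a multi-tissue, multi-gestational-week design,
    clustering of called CpGs into regions (tHRs and dDMRs) by a
    consecutive-CpG rule, CpG-island shore/shelf and genic annotation,
    odds-ratio enrichment against annotation axes and chromatin-state
    segmentations, an empirical permutation test for overlap between
    called regions and transcription-factor binding peaks, counts-per-
    million expression trend summaries with a direction test, and a
    synthetic-data generator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
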