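Package: rhdamp
Title: Noninvasive Fetal RHD Genotyping from Amplicon Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for amplicon sequencing-based noninvasive
    fetal RHD genotyping from cell-free DNA. Merges paired-end reads with a
    zero-mismatch overlap policy, filters by amplicon size and base quality,
    optionally extracts 12-base unique molecular identifiers (UMIs) and
    collapses PCR duplicates, assigns each read to one of four co-amplified
    paralogous regions (upstream/downstream Rhesus boxes, RHD exon 9, RHCE
    exon 9) by diagnostic bases, computes per-position base counts and
    error-ratio statistics, and infers the maternal RHD genotype and the
    fetal RhD status with a mixture-fraction estimate. Ships a synthetic
    read simulator with ground truth so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
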