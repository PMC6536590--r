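Package: regulonmap
Title: Regulon Mapping from ChAP-Seq Coverage and Transcriptome Overlay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the regulon of a bacterial transcription factor
    from chromatin affinity purification sequencing (ChAP-Seq) coverage
    tracks and two-condition expression data. Coverage is smoothed with a
    rolling mean (window 50 bp, step 10 bp), binding peaks are called where
    smoothed coverage exceeds threefold the genome-wide mean, 100-bp
    summit-centered windows are extracted, and a palindromic AT-rich binding
    motif is inferred with a zero-or-one-occurrence-per-sequence (ZOOPS)
    expectation-maximization finder. Peaks are assigned to candidate target
    promoters and joined with differential-expression statistics to classify
    direct targets. A synthetic-data module plants binding sites with known
    ground truth so the whole pipeline is testable end to end, and helpers
    cover qRT-PCR relative quantification (2^-dCt) and flow-cytometry
    reporter gating against an uninduced negative control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
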