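Package: lncduplex
Title: Discovery and Regulatory Annotation of lncRNA-RNA Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies long non-coding RNAs (lncRNAs) from annotated
    transcriptomes and expression data, discovers candidate lncRNA:RNA
    duplexes by local complementarity alignment with a wobble-aware
    scoring scheme (G:C = 4, A:T = 2, G:U = 1, affine gap costs), and
    assigns each duplex to candidate regulatory mechanisms: modulation
    of alternative splicing, miRNA target-site masking, triggering of
    A-to-I editing, and Staufen-mediated decay via Alu elements in
    3' UTRs. Includes condition-specific interaction filtering,
    overlapping-loci concordance statistics, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
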