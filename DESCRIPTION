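Package: karyoscreen
Title: Karyotype Recurrence, FISH Fusion Calling, and Breakpoint-Window
    Expression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the cytogenetic and transcriptomic readouts of an
    in vitro model of Barrett's-esophagus carcinogenesis: an ISCN
    karyotype parser with recurrence mining across replicate cultures, a
    per-nucleus dual-color FISH signal classifier with sample-level
    translocation-fusion calls, an FPKM median-normalization and signed
    fold-change screen for genes inside translocation-breakpoint windows
    (2p22, 10q22, 16q22; Hg19), and a synthetic-data generator with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
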