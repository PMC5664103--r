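Package: exonizeL1
Title: Characterization of Intronic LINE-1 Insertions Causing Exonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize deep-intronic LINE-1 (L1) retrotransposon
    insertions that become partially exonized through cryptic splice-site
    recognition, as seen in large disease genes such as dystrophin. The
    pipeline discovers an unknown insertion by comparing an observed
    transcript against the reference mRNA, classifies the inserted sequence
    against a bundled repeat-consensus panel by local alignment, localizes
    candidate cryptic acceptor sites by AG+prefix motif scanning with
    position-weight-matrix acceptor and branch-point scoring, maps the
    genomic 5'/3' element junctions with target-site-duplication and poly-A
    detection, annotates element architecture (5'UTR, ORF1, ORF2, 3'UTR,
    poly-A) and subfamily, and predicts the protein-level frameshift
    consequence in HGVS notation. A seeded synthetic-locus simulator
    provides ground truth for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
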