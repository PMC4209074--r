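Package: ahltools
Title: Motif Typing, Classification and Gene-Tree Reconciliation for the
    AHL Transcription-Factor Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signature-based detection and typing of AT-hook motifs and PPC
    (DUF296) domains in plant protein sequences, rule-based classification of
    AHL (AT-hook Motif Nuclear Localized) proteins into Type-I/-II/-III with
    clade assignment and intron-consistency checks, duplication-loss parsimony
    reconciliation of rooted gene trees against a species tree via LCA mapping
    with per-lineage event summaries and ortholog/paralog calls, and a
    birth-death gene-family simulator with logged true event histories for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    S4Vectors,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
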