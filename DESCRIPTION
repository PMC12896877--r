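Package: xkmir
Title: Cross-Kingdom miRNA Mimicry Screening and Target-Overlap Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Screens plant mature miRNAs against a host miRNA catalogue for
    sequence mimicry using a global Needleman-Wunsch aligner with a
    mismatch-averse substitution scheme and a strict 6mer seed-alignment
    filter; predicts putative targets of each miRNA on host 3'UTRs by
    canonical seed-site scanning (6mer, 7mer-A1, 7mer-m8, 8mer); tests
    whether candidate mimic pairs share more predicted targets than expected
    by chance with a one-sided Fisher exact test; and runs hypergeometric
    over-representation analysis of target sets against a flat term
    annotation with Benjamini-Hochberg adjustment. Includes a seeded
    synthetic-data generator that plants mimic pairs, target sites and
    enriched terms with known truth, so every stage of the pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
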