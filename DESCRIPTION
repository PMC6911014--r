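Package: benstone
Title: Binding Symmetry and Insulation Analysis for BEN-Solo Chromatin Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterizing chromatin insulator proteins
    from ChIP-seq, ChIP-nexus, PRO-seq and RNA-seq style data. Implements
    strand-asymmetry orientation-index analysis of ChIP-nexus footprints,
    summit-distance peak overlap and co-occupancy partitioning, IUPAC
    consensus motif scanning and enrichment summaries, promoter-proximal
    quantification of nascent transcription, the adjacent-promoter-pair
    insulation contrast with a Monte-Carlo genomic placement null, and a
    three-group de-repression contrast of direct targets. Ships a synthetic
    data generator that emulates all required inputs so every analysis is
    testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
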