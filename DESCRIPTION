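Package: poolability
Title: Read Loss, Read Separation and Copy-Number Analysis for Pooled
    Multi-Organism Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess whether samples of different organisms can be
    pooled before library preparation and separated bioinformatically after
    sequencing. Enumerates all possible reads of a given length over a set
    of bacterial replicons, classifies each read as uniquely mappable or
    ambiguous within its own organism (intra-organism repeats) and across a
    pool (inter-organism homologies), resolves the resulting read loss at
    organism and gene level, quantifies sequencing-error-driven
    misassignment between pooled organisms under a unique-best-match
    criterion, and performs marker-frequency analysis (per-replichore
    log-linear regression of coverage) to estimate origin/terminus copy
    numbers. Includes a synthetic-data generator for genomes with planted
    repeats, homologous segment pairs, gene annotations and replication
    coverage gradients, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
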