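Package: peakgain
Title: Differential Histone-Mark Peak Analysis Integrated with Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for comparing ChIP-seq peak sets between two conditions
    and integrating the result with gene expression. Partitions peaks into
    condition-specific and common sets by minimum-overlap criterion, annotates
    peaks to genomic features with fixed precedence, profiles binned coverage
    around TSS/TES anchors, classifies genes as having gained or lost signal
    in TSS versus gene-body regions, intersects those calls with
    fold-change-defined differentially expressed genes within a distance
    bound, and runs hypergeometric term enrichment with Benjamini-Hochberg
    correction. Includes a deterministic synthetic-experiment generator with a
    machine-readable truth table so every stage is verifiable offline, plus
    ChIP-qPCR percent-input quantitation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
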