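Package: bsamap
Title: Bulked-Segregant QTL-Seq Scanning and Map-Based Cloning of EMS Mutants
Version: 0.1.0
Authors@R:
    person("BSA", "Maintainers", email = "maintainers@bsamap.org", role = c("aut", "cre"))
Description: Tools for mapping causal mutations in F2 populations of selfing
    crops by bulked-segregant whole-genome sequencing (QTL-Seq) followed by
    recombinant-based fine mapping and candidate-gene triage. Implements
    per-site SNP-index and delta(SNP-index) statistics with a simulation-based
    confidence band, sliding-window scans and candidate-region calling;
    SPAD-based phenotype classification, recombinant screening and
    marker-interval narrowing; EMS-consistency variant-effect annotation and a
    candidate-filter cascade; a simplified differential-expression stage and
    2^-ddCt relative expression; KASP/PARMS-style fluorescence genotype calling
    with cosegregation and Mendelian segregation checks; and read-level QC
    filters. A forward simulator for F2 meiosis, phenotype-selected bulks and
    pooled sequencing depths makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    withr,
    optparse,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
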