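Package: sigconn
Title: Connectivity Scoring of Drug-Response Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow for in-silico drug-synergism screening
    by transcriptional signature matching. Builds drug-response gene
    signatures from treated-versus-control expression matrices (quantile
    normalization, moderated-t differential expression, top up/down tag
    selection), scores them against a CMap-style reference compendium of
    z-score profiles with a Kolmogorov-Smirnov-type connectivity engine
    (enrichment score, WTCS, cell-line-normalized NCS, tau percentile),
    selects genes coherently modulated by query and compound, and annotates
    them by Ward clustering and hypergeometric pathway enrichment. Includes
    synthetic-data generators with planted ground truth for end-to-end
    validation, and readers/writers for GCT 1.2/1.3, GMT and
    GSE92742-convention metadata tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    limma,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
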