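Package: scHomology
Title: Cross-Species Cell-Type Homology Mapping from Single-Cell Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping homologous cell types between two species from
    single-cell RNA-seq data. Resolves many-to-many ortholog candidate tables
    into strict one-to-one gene maps, applies per-library cell quality
    filters, aggregates single cells into pseudo-bulk and pseudo-cell
    profiles, matches cell types across species with a neighbor-voting AUROC
    statistic, scores cross-species marker-set enrichment with a rank-based
    gene-set variation statistic, and fuses both arms into a conservation map
    of retained homologous cell-type pairs. Includes a seeded two-species
    simulator with planted homology for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr,
    tools
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
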