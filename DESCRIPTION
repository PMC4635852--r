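Package: exprSubtypes
Title: Molecular Subtype Discovery in Expression Profiles of Graft Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers molecular subtypes within a histologically uniform
    diagnosis from a gene-by-sample expression matrix. Implements the full
    workflow: coefficient-of-variation and scaled-expression gene filtering,
    per-gene z-score normalization, outlier-sample removal by classical
    multidimensional scaling with intracentroid distance z-scores,
    unsupervised hierarchical clustering validated by connectivity, Dunn and
    silhouette indices, two-group differential expression with
    Benjamini-Hochberg false discovery rate control, partitioning of genes
    into core and subtype-unique sets, hypergeometric gene-set
    over-representation, pathway-overlap networks, and induced interaction
    modules over protein-protein, regulatory and drug-target edge lists.
    Ships a synthetic-data generator that plants recoverable subtypes,
    outliers and differentially expressed gene classes so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
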