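Package: sedabench
Title: Benchmarking Beta-Diversity Workflows and Transfer Functions for
    Sedimentary Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates structured community count matrices (cluster and
    gradient settings), injects sedimentary ancient DNA style taxon-dropout
    noise with depth-preserving read reallocation, and benchmarks grids of
    count transformations, beta-diversity indices and two-dimensional
    ordinations by PERMANOVA pseudo-F. Also evaluates KNN and random-forest
    transfer functions trained on modern samples and applied to degraded
    samples, on composition matrices or on ordination embeddings, with
    repeated cross-validation, top-approach aggregation and Tukey HSD
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    phangorn,
    Biostrings,
    edgeR,
    Rtsne,
    uwot,
    randomForest,
    class,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    phyloseq,
    SummarizedExperiment
Config/testthat/edition: 3
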