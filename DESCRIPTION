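Package: fetomod
Title: Fetoplacental Co-Expression Modules, Expression Polygenic Scores and
    Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing placental gene co-expression modules to adult
    health outcomes. Implements signed weighted co-expression network
    construction (biweight midcorrelation, soft thresholding, topological
    overlap, tree cutting and eigengene merging), permutation Zsummary module
    preservation between datasets, eQTL-weighted expression polygenic scores
    with LD clumping and negative controls, single-sample gene-set enrichment
    (ssGSEA) and cell-level module scores, a PHESANT-style phenome-wide
    association scan, two-sample Mendelian randomization (IVW, weighted
    median, MR-Egger) with sensitivity analyses, Fisher's exact gene-set
    overlap, and ARACNE-style mutual-information connectivity. A synthetic
    genotype-to-expression-to-phenotype generator with planted modules,
    cis-eQTLs and causal effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
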