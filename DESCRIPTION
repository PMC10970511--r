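Package: pooltox
Title: Multi-Lot Pooled-Hepatocyte Toxicogenomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-lot pooled-hepatocyte toxicogenomics
    studies of hepatotoxicant exposure. Computes per-lot log2 fold changes and
    differential-expression calls (Welch t-test, Benjamini-Hochberg FDR),
    scores gene sets (liver injury modules, pathways, toxicity feature sets)
    with aggregated fold-change statistics against permutation nulls, and
    quantifies lot-to-lot consistency (differential-expression overlap, common
    genes, merged fold changes, correlation matrices, standard-deviation
    profiles, and gene-panel tables). Includes a synthetic multi-lot study
    generator with known ground truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
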