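Package: glycohub
Title: Glycogene Hub Discovery from Integrated Bulk and Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying upstream glycosyltransferase hub genes and
    their downstream cell-cell signaling from case/control brain expression
    cohorts. Implements per-gene standardized-mean-difference (Hedges' g)
    random-effects meta-analysis across cohorts and regions, hypergeometric
    over-representation analysis and preranked gene set enrichment with a dual
    post-hoc glycosylation-pathway test, pathway-glycogene bipartite hub
    ranking, pathway-activity PCA regression with Fisher p-value combination,
    single-cell normalization, marker detection and ligand-receptor
    communication scoring, and co-expression network propagation (topological
    overlap, percentile thresholding, random walk with restart). Includes
    seed-deterministic synthetic-data generators with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
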