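Package: cortexmap
Title: Dense Transcriptional Cartography on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spatially dense gene-expression maps (DEMs) on triangulated
    cortical surface meshes from sparse multi-donor postmortem samples, and
    provides the downstream statistical machinery for analysing them:
    spherical-rotation ("spin") permutation null models, transcriptional
    distinctiveness peaks, per-gene expression gradient fields and their
    alignment with cortical folding, spatial co-expression modules with
    topological-overlap clustering, and resampling-based gene-set enrichment
    statistics. A synthetic-cortex generator with planted ground truth makes
    every pipeline stage testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    mgcv,
    minpack.lm,
    jsonlite,
    xml2,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
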