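Package: velocts
Title: Composite Transition Scores from RNA Velocity Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Summarizes grid-aggregated RNA velocity arrows in a low-dimensional
    embedding (e.g. UMAP) into a directed cluster-to-cluster composite
    transition score (CTS) matrix, using the geometric alignment of each arrow
    with the direction towards destination-cluster centroids, a distance-based
    weighting of cluster pairs, and multi-perspective aggregation for 3D
    embeddings. Also provides the accompanying single-cell quality-control
    filters for B-cell data (lineage-marker exclusion, minimum gene counts,
    top-percentile transcript-count removal) and immunoglobulin/T-cell-receptor
    variable-gene pruning, plus a synthetic flow-field generator with a known
    ground-truth transition graph for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
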