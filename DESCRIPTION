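Package: lrnet
Title: Ligand-Receptor Cell-to-Cell Communication Networks from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts, weights, summarises, compares and visualises directed
    cell-to-cell communication networks from single-cell or bulk expression
    data using a curated ligand-receptor pair database. Edges between ordered
    cell-type pairs are weighted by mean expression, expression specificity
    and total expression; per-dataset networks can be collapsed into directed
    cell-connectivity summaries, compared across two conditions (shared and
    condition-exclusive edges, fold-change and difference delta networks),
    and interrogated for autocrine, intra-organ and inter-organ signalling
    against a degree-preserving permutation null. Includes a seeded synthetic
    single-cell count generator with planted communication structure for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
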