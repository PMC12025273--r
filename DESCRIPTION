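Package: dims
Title: Driver-Induced Modular Screening for Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects treatment-specific gene co-expression modules (soft
    thresholding, topological overlap, hierarchical clustering), classifies
    drug-responsive (On) and synergistic (Sy) modules with a permutation
    Zsummary preservation statistic, screens differentially expressed genes,
    quantifies target-set separation (S_AB, 'closest' distance) on an
    interaction network, and ranks driver genes by module shortest distance
    and flow centrality. Ships a synthetic-data generator with planted
    modules, planted disruptions, planted differential expression and planted
    network bridge nodes so the whole screen is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
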