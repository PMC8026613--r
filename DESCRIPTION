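Package: canvasnet
Title: Multiscale Promoter-Interaction Networks from Promoter-Capture Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and compares two-condition promoter-interaction networks
    from promoter-capture Hi-C significant-interaction calls at restriction
    fragment resolution. Merges per-condition CHiCAGO-scored calls into a single
    graph with edge- and node-level condition specificity, enumerates
    sub-networks and modularity-based communities, annotates fragments with
    reduced chromatin states, calls stitched enhancers and super-enhancers from
    H3K27ac peaks with a rank-curve cutoff, assigns enhancer target genes
    through the interaction network, constructs composite OCT4/SOX2/NANOG
    occupancy peaks and tests the association between occupancy change and
    interaction rewiring. Includes deterministic force-directed and
    multidimensional-scaling layouts, genomic permutation overlap tests, a
    seeded synthetic study generator, and GEXF/GraphML/TSV network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    igraph,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
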