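Package: goldclust
Title: Nanocluster and Coclustering Analysis of Immunogold Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial statistics for immunogold electron microscopy of intact
    plasma-membrane sheets. Implements univariate Ripley K-function
    nanoclustering analysis with Monte Carlo confidence-envelope
    standardization and the Lmax summary statistic, bivariate (two gold
    sizes) coclustering analysis with the integrated L-bivariate (LBI)
    statistic, local L(r) - r oligomer classification into monomers, dimers
    and higher-order nanoclusters, and seeded synthetic pattern generators
    for validating every stage. Also provides the set computations used to
    build proximity-proteomics interaction maps: SAINT-score filtering,
    fold change over control, asymmetric overlap fractions and Venn
    partitions of bait prey lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
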