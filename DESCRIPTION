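Package: hicwavelets
Title: Multi-Scale Structural Domain Mining in Hi-C Contact Maps with
    Spectral Graph Wavelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosome structural domains from Hi-C contact
    matrices at many scales simultaneously. Each intra-chromosomal
    contact matrix is treated as the weighted adjacency matrix of a
    locus interaction network; spectral graph wavelets probe the
    neighbourhood of every locus at ~100 logarithmically spaced scales,
    and average-linkage clustering of the wavelet correlation distance
    yields one community partition per scale. Communities are reduced
    to genomic interval-communities, de-duplicated into a hierarchical
    border database, and compared against external domain sets (e.g.
    TAD calls) with mutual-coverage and border-matching statistics.
    Includes a fast random-vector Chebyshev estimator of the wavelet
    correlation matrix, an exact eigendecomposition oracle, nested
    block-matrix simulators for validation, and an insulation-ratio
    diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
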