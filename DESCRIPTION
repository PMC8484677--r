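Package: hocorr
Title: Kernel-Based Dynamic and Higher-Order Correlations in
    Multivariate Timeseries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Timepoint-by-timepoint estimation of dynamic correlations in
    multivariate timeseries using per-timepoint weighting kernels (uniform,
    Dirac delta, Gaussian, Laplace, Mexican hat), together with dynamic
    inter-subject functional connectivity (DISFC) across groups of
    participants, low-dimensional projection of correlation streams by PCA
    or per-timepoint eigenvector centrality, and recursive estimation of
    arbitrarily high-order correlations in linear space. Includes
    simulators for multivariate Gaussian timeseries with known dynamic
    first-order and higher-order (Kronecker-structured) correlations,
    recovery benchmarks against the simulated ground truth, and an
    across-participant temporal decoding procedure with simplex-constrained
    feature-order weight optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
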