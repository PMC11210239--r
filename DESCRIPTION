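Package: hrspls
Title: Hypergraph-Regularized Sparse Partial Least Squares for Paired Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers correlated co-modules (joint feature sets plus their
    supporting samples) between two omics matrices measured on the same
    samples, such as gene expression and DNA methylation. Fits sparse
    partial least squares components whose weight vectors are additionally
    smoothed over k-nearest-neighbour hypergraphs built on the feature
    profiles of each block, extracts modules by z-score thresholding of
    weights and latent scores, and deflates to obtain successive modules.
    Includes plain PLS, sparse PLS and simple-graph-regularized baselines,
    module diagnostics (Pearson correlation, reconstruction error),
    hyperparameter grid search, a synthetic generator with planted
    co-modules and recovery metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
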