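Package: hogsvd
Title: Higher-Order Generalized Singular Value Decomposition for
    Multi-Dataset Expression Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact joint factorization of two or more real matrices that
    share a column dimension but not a row dimension, as arises when
    comparing genome-scale expression time courses across organisms whose
    gene sets cannot be mapped onto each other.  Each matrix is factored
    as D_i = U_i Sigma_i t(V) with a single shared right basis V obtained
    from the eigensystem of the arithmetic mean of all pairwise Gram-matrix
    quotients.  Eigenvalues equal to one identify a common subspace of
    right basis vectors that carry equal significance in every dataset;
    the package identifies that subspace, reconstructs each dataset inside
    it to strip dataset-exclusive artifacts, projects arrays and genes
    onto the two-dimensional plane that approximates it for angular
    (phase) classification, and scores annotation enrichment of the
    leading genes of each left basis vector with exact hypergeometric
    tail probabilities.  Includes tab-delimited table readers/writers, a
    command-line interface and a synthetic-data generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
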