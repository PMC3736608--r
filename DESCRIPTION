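Package: nmfbox
Title: Non-Negative Matrix Factorization Toolbox for Biological Data Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-level toolbox for non-negative matrix factorization (NMF)
    of gene expression and other feature-by-sample matrices. The numerical
    level provides active-set solvers for non-negative quadratic programming
    (NNQP), non-negative least squares (NNLS) and l1-regularized QP, plus
    multiplicative-update engines powering standard NMF, semi-NMF,
    sparse-NMF, versatile sparse matrix factorization (VSMF), convex-NMF,
    orthogonal tri-factor NMF, weighted NMF for missing data, and their
    kernelized counterparts. The mining level offers NMF consensus
    clustering with dispersion-based rank selection, biclustering, feature
    extraction, entropy-based factor-specific gene selection, an NNLS
    sparse-representation classifier robust to missing values, and
    statistical comparison of classifiers (Friedman and post-hoc Nemenyi
    tests, learning-curve fitting, minimum significant sample size).
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
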