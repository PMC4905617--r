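Package: codivar
Title: Common and Distinctive Variation Decomposition of Linked Data Matrices
Version: 0.1.0
Authors@R:
    person("codivar", "maintainers", email = "codivar@example.org",
           role = c("aut", "cre"))
Description: Decomposes two column-linked numeric data matrices that share
    their object (row) mode into common, distinctive and residual variation
    using three multi-block factorization methods: DISCO-SCA (simultaneous
    component analysis followed by orthogonal rotation towards a zero-pattern
    target), JIVE (alternating estimation of joint and individual low-rank
    structure with permutation-based rank selection) and O2-PLS (covariance
    SVD with per-component removal of orthogonal variation). Includes the
    model-selection procedure of each method, method-agnostic diagnostics
    (orthogonality pattern audit, explained and cross-over variance,
    column-space projection residuals, SWISS and modified RV coefficients),
    a synthetic-data generator for planted common/distinctive structure, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
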