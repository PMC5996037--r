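Package: celldecon
Title: Immune Cell-Type Deconvolution from Bulk RNA-Seq Signature Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds immune cell-type signature gene matrices from labeled
    pure-cell RNA-Seq count data using voom-based moderated differential
    expression and fold-change ranking, and estimates relative cell-type
    proportions in bulk tissue or tumor expression profiles under a linear
    mixing model. Six regression back-ends are provided (linear least
    squares, constrained quadratic programming, ridge, lasso, elastic net,
    and nu-support-vector regression), together with a synthetic-mixture
    simulator with tumor spike-in and a benchmarking harness scoring
    predicted against true mixing fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    glmnet,
    e1071,
    quadprog,
    ggplot2,
    yaml,
    withr,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
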