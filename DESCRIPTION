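Package: fusecell
Title: Gene Fusion Detection from Full-Length Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene fusions from full-length single-cell RNA-seq by
    jointly analysing the chimeric alignment evidence of all cells of a
    sample. Split-mapped and discordant reads between distinct genes are
    clustered into fusion candidates, the technical chimeric background is
    modelled with a covariate-dependent zero-inflated negative binomial
    regression (spline GC term, linear partner-expression terms), candidate
    significance is assessed by resampling from the fitted background with
    an empirical two-subset false discovery rate procedure, and residual
    sequence artifacts are removed with a bi-directional LSTM junction
    classifier trained on a proxy task. A PCR mis-priming chimera simulator
    generates synthetic datasets with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    splines,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
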