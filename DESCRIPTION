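Package: sharedcfdr
Title: Conditional False Discovery Rates for GWAS Pairs with Shared Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates conditional false discovery rates (cFDR) for pairs of
    genome-wide association studies whose case-control designs share some or
    all control subjects. Shared controls induce a positive correlation
    between the studies' null Z scores, which biases the naive cFDR estimator
    downward; this package computes the shared-control "expected quantile"
    correction from a two-component normal mixture model of conditional-trait
    effect sizes fitted by expectation-maximisation, calibrates significance
    thresholds against the genome-wide convention, constructs the rejection
    region in the p-value unit square and bounds the overall false discovery
    rate across it, and provides downstream multiple-testing correction,
    LD-based pruning, pleiotropy summaries, and a simulator that reproduces
    the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
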