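Package: orgretain
Title: Quantifying Retention of In Vivo Transcriptional Features in
    Intestinal Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for comparing bulk transcriptomes of
    intestinal crypts (in vivo) with organoids cultured from them
    (in vitro). Provides a negative-binomial count simulator with a full
    factorial design (sample type, gut compartment, gender, age) and
    planted cell-type mixture structure; size-factor normalization and a
    per-gene negative-binomial Wald test; principal-component variance
    decomposition with factor-association tests and
    highly-contributing-gene selection; single-cell reference
    construction (normalization, k-means clustering, marker definition,
    signature matrix); non-negative least-squares cell-type
    deconvolution with simulated-mixture validation; weighted
    running-sum gene-set enrichment with permutation p-values and
    directional Z-score summaries; and a DEG-matrix effect-size
    framework that measures, as an adjusted R-squared, how much of each
    in vivo biological feature survives in culture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
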