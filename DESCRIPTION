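Package: ordipa
Title: Parallel Analysis of Ordinal Items with Smoothed Polychoric Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the dimensionality of sets of ordered categorical items by
    permutation-based parallel analysis of Pearson and polychoric correlation
    matrices. Polychoric correlations are estimated with a two-step maximum
    likelihood procedure using item-pair-specific thresholds; indefinite
    correlation matrices can be smoothed to positive definiteness by alternating
    projections in the Frobenius norm, by eigenvalue clipping, or by rescaling of
    Heywood-type variables located through minimum trace factor analysis.
    Retention criteria include the mean and the 95th percentile of the
    permutation eigenvalue distribution, for principal components as well as
    principal axis factoring with squared-multiple-correlation communalities.
    A Monte-Carlo engine reproduces factorial simulation studies over ordinal
    factor models with major, minor and unique factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
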