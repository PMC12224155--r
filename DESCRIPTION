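Package: alspace
Title: Active Learning for Chemical Space Expansion of Ionization
    Efficiency Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pool-based active learning (AL) workflows for expanding the
    chemical-space coverage of electrospray ionization efficiency (log IE)
    regression models used in nontargeted LC/HRMS screening. Provides
    descriptor cleaning (near-zero variance and pairwise-correlation
    filters with protected eluent features), Euclidean chemical-space
    overlap diagnostics (d_NN=5), a gradient-boosted log IE regressor with
    quantile-regression-forest prediction intervals, five batch sampling
    strategies (random, clustering-based, uncertainty-based,
    anticlustering, and a sparse/dense mix) plus cost-based selection,
    campaign orchestration with pooled-RMSE evaluation over repeated
    splits, space-separated cross-validation, standard-free quantification
    from predicted log IE with fold-error statistics, and a synthetic
    chemical-space generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
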