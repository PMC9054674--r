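Package: roimeta
Title: Multi-Site Meta-Analysis of Regional Brain Morphometry with
    Spatially Constrained Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analyzing associations between a continuous
    trait and parcel-wise brain morphometry across heterogeneous imaging
    sites. Computes covariate-adjusted partial correlations per site and
    region, pools them with random-effects models (DerSimonian-Laird and
    REML) including categorical moderator tests and Benjamini-Hochberg
    false discovery rate control, and assesses spatial similarity between
    effect-size maps with spin permutation tests (cortical) or label
    shuffling (subcortical) plus Steiger comparisons of dependent
    correlations. A synthetic-data module generates multi-site cohorts
    with planted, spatially autocorrelated effects so the full pipeline
    can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
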