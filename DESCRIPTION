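Package: ensdm
Title: Ensemble Species Distribution Modelling with Range-Change Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building skill-gated, weighted-average ensembles of
    species distribution models (SDMs) and quantifying projected habitat
    range change. Implements occurrence thinning to the analysis grid,
    random pseudo-absence sampling, Pearson/VIF predictor screening,
    native logistic-regression (GLM) and surface-range-envelope (SRE)
    learners behind a pluggable learner registry, presence-absence skill
    metrics (sensitivity, specificity, Cohen's kappa, TSS, rank-based AUC)
    with TSS-maximising cutoff selection, suitability classing into
    unsuitable/low/moderate/high bands, latitude-corrected spherical cell
    areas, and loss/stable/gain range-change summaries under future
    climate scenarios. A synthetic-data module generates standardized,
    partially collinear environmental stacks with a known logistic niche
    so the whole pipeline is testable end to end without external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
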