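Package: sbpatterns
Title: Diurnal Sedentary-Behavior Pattern Clustering and Physical-Functioning Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives diurnal sedentary-behavior (SB) patterns from hip-worn
    accelerometer count data using a two-phase clustering procedure: Phase I
    clusters wake-aligned day-level SB trajectories with longitudinal k-means
    selected by the Calinski-Harabasz criterion; Phase II clusters participants
    by their day-cluster proportions with complete-linkage hierarchical
    clustering selected by average silhouette width. Includes Choi non-wear
    detection, sleep-log bed-time resolution, intensity cutpoint
    classification, adherence filtering, Copy-Mean trajectory imputation, a
    linear mixed-model association stage linking patterns to longitudinal
    physical-functioning trajectories with MVPA effect modification, and a
    synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
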