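Package: sepsubtype
Title: Sepsis Plasma Proteome Subtyping and Minimal-Panel Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised discovery of sepsis plasma proteome subtypes from
    day-1 protein intensity matrices (completeness filtering, median
    imputation, z-standardization with day-1 parameter transfer, PCA and
    k-means with silhouette, gap-statistic and Davies-Bouldin diagnostics),
    nearest-centroid projection of day-4 samples and subtype trajectory
    tabulation, per-protein differential abundance with an ANOVA/Tukey/
    fold-change significance gate and abundance-pattern clustering, clinical
    characterization (per-subtype summaries, Kruskal-Wallis with Dunn's
    post-hoc test, chi-squared and Fisher contingency tests, Kaplan-Meier
    survival), and a minimal protein-panel random-forest classifier built by
    Shapley-ranked Monte Carlo cross-validated feature selection with
    knee-point panel sizing. Includes a synthetic-cohort generator that
    emulates the statistical structure of a multicentre sepsis cohort so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    survival,
    ranger,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr
Config/testthat/edition: 3
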