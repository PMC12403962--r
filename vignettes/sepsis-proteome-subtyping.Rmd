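---
title: "Plasma proteome subtyping of sepsis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma proteome subtyping of sepsis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sepsubtype` implements an end-to-end analysis of early-sepsis plasma
proteomes: unsupervised discovery of patient subtypes from day-1 protein
intensities, projection of day-4 follow-up samples into the frozen day-1
model, differential-abundance characterization of the subtypes, clinical and
survival statistics, and a minimal protein-panel random-forest classifier
sized by knee-point detection on a Monte-Carlo-cross-validated recall curve.
This vignette explains the statistical procedures, the tunable parameters
and their defaults, the synthetic-cohort generator the tests run against,
and the design decisions taken where the procedure was genuinely open.

## The subtype model

Input is a proteins x samples matrix of log2-scale, batch-normalized DIA
protein intensities with explicit missing values, one day-1 sample per
patient and one day-4 sample for a subset. The discovery chain is:

1. **Completeness filter.** Keep proteins quantified at both timepoints
   with a missing fraction *strictly below* 30% at day 1 and at day 4
   (`max_missing = 0.30`). Correlated proteins are deliberately retained at
   this stage; pruning happens only in the supervised arm.
2. **Median imputation**, per protein, within each matrix separately:
   day-1 medians fill day-1 holes, day-4 medians fill day-4 holes. The
   alternative — imputing day 4 with day-1 medians — would leak day-1
   values into follow-up samples of patients who may have left the cohort,
   so the per-matrix rule is used and declared here.
3. **z-standardization with parameter transfer.** Per-protein mean and
   *population* (ddof = 0) standard deviation are estimated on day 1 only
   and applied unchanged to day 4. Day-4 columns are never re-centred: a
   genuine global day-4 shift is information, not nuisance. The population
   variance convention matches the fit/transform scalers standard in this
   kind of pipeline and is recorded in the serialized model.
4. **PCA.** Components are added until the cumulative explained-variance
   fraction strictly exceeds `variance_target = 0.70`. Eigenvector signs are
   fixed by making each loading's largest-magnitude entry positive, so
   serialized models are comparable across runs.
5. **k-means** on the PC scores: k-means++ seeding, Lloyd iterations
   (`iter_max = 300`), `n_init = 25` restarts keeping the lowest total
   within-cluster sum of squares; runs converging to an empty cluster are
   re-seeded. The cluster count is always taken from configuration
   (default `k = 4`); the diagnostics below are advisory, mirroring a
   workflow in which biological interpretability co-decides k.
6. **Severity relabelling.** Clusters are renamed 0..k-1 by strictly
   decreasing median day-1 SOFA score, so label 0 is always the most severe
   subtype; ties go to the smaller cluster first, then the original index.
7. **Day-4 assignment.** Day-4 (or new) samples are imputed, standardized
   and projected with the frozen day-1 parameters and assigned to the
   nearest centroid in Euclidean distance, ties to the lowest
   severity-ordered label. The `subtype_model` object is read-only after
   fitting; nothing downstream ever refits it.

### Cluster-count diagnostics

`choose_k()` reports, per candidate k: mean silhouette width,
Davies-Bouldin index, and the gap statistic with its simulation standard
error. The gap reference distribution is uniform over the bounding box of
the PC scores — the simpler of the two canonical variants — with
`B_reference = 50` draws and squared-distance within-cluster dispersion; the
suggested k follows the usual one-standard-error rule (smallest k with
Gap(k) >= Gap(k+1) - s(k+1)), which alone also evaluates k = 1.

## Differential abundance

Per protein, a one-way fixed-effects ANOVA across subtypes on log2
intensities, Benjamini-Hochberg correction with the number of testable
proteins at that timepoint as denominator (day 1 and day 4 are corrected
separately), Tukey's studentized-range post-hoc test (Tukey-Kramer form for
unequal group sizes), and per-pair ratios of means computed on the linear
scale (`2^x`), lower-numbered subtype in the numerator. A pair is
significant iff all three conditions hold — ANOVA p_FDR <= 0.05, pair
p <= 0.05, RoM >= 1.5 or <= 0.67 — and a protein iff any pair is. Whether
the post-hoc and fold-change condition must coincide on the *same* pair is
an interpretation; the conjunctive per-pair reading is implemented. Testing
on log2 and fold changes on the linear scale keeps the tests
variance-stable and the RoM interpretable; both scales appear in the
output. Proteins with fewer than two observations in any subtype, or zero
within-group variance, are flagged untestable and excluded from the FDR
denominator.

Significant proteins are grouped into abundance patterns by hierarchical
clustering of their z-scored subtype-mean profiles with dissimilarity
1 - Pearson correlation and Ward linkage (the Lance-Williams Ward update
applied directly to the correlation dissimilarities). Ward's method
formally assumes squared Euclidean distances, so this combination is
improper in the strict sense; it is implemented as specified because it is
the procedure being reproduced, and the tree is only used to cut pattern
branches (five at day 1, four at day 4 by default), labelled by decreasing
size.

## Clinical statistics

Repeated same-day observations collapse by a per-variable registered rule
(median, minimum or maximum — the clinically informative direction, e.g.
maximum for creatinine). Summaries are 25th/50th/75th percentiles with the
type-7 linear-interpolation quantile convention (declared because IQR
endpoints depend on it); categorical summaries always report their actual
non-missing denominators. Numeric variables use Kruskal-Wallis with
tie-corrected Dunn post-hoc z tests, Bonferroni-multiplied by the number of
pairs and capped at 1. Categorical variables use the chi-square test
without continuity correction when all expected counts are at least 5 and
Fisher's exact test otherwise (the >= 5 switching rule is this package's
choice). Omnibus p-values are reported raw. Survival uses the product-limit
estimator censored at 30 days, plus the table statistic median (IQR) death
day among deceased patients only. All tests are two-sided.

## The classifier arm

The feature table contains subtypes 1-3 only (the most severe subtype is
too small for robust modelling). Immunoglobulin protein entries (gene
prefixes IGH/IGK/IGL plus JCHAIN) are removed and replaced by routine
turbidimetric IgG/IgA/IgM concentrations; proteins covered by routine
assays (CRP, FGG, FGA, FGB, HBA2, HBB, HBD) are excluded; columns with more
than 30% missingness are dropped; clinical features must separate the three
subtypes at Kruskal-Wallis p < 0.05; and correlated features are pruned
greedily at |r| > 0.7 in scan order Ig, proteins, clinical — the Ig columns
are scanned first because they are fixed members of the final panel and
must never lose a pruning duel to a protein.

Feature importance is ranked by SHAP values: per MCCV iteration (stratified
80/20 split, median imputation fitted on the training part and applied to
both), a random forest is fitted on all features and each feature's mean
absolute Shapley attribution is computed on the held-out part with the
path-dependent TreeSHAP algorithm, implemented in C++ against the exported
tree structures with node covers recomputed from the training data.
Attribution on the held-out part rather than the training part is a
declared choice. Features are ranked within their domain (medical,
protein); the Ig columns form a third, fixed domain that is present in
every model and never ranked. The median rank across iterations orders the
nested scan: an outer loop over the number of medical features and an inner
loop over the number of proteins, each cell scored by mean +/- SD weighted
test recall over the MCCV splits (common splits across cells, so adjacent
cells are paired).

The panel size is the Kneedle knee of the proteins-only recall curve
(`n_medical = 0`): min-max normalize both axes, take the arg-max of
y - x (sensitivity 1, no smoothing); flat, linear or monotone-decreasing
curves have no knee and return NA. The knee is computed on the
proteins-only curve because the panel deliberately contains no clinical
features — at the knee, adding them yields only marginal gains. The final
panel is the knee-count proteins most frequently appearing in the
per-iteration top-knee rank sets (ties by better median rank), plus IgG,
IgA and IgM. Evaluation reports accuracy, macro one-vs-rest AUROC (macro
chosen because the reference reports a single AUROC without declaring a
scheme; micro averaging is available), weighted F1, multiclass MCC in
Gorodkin's covariance form, weighted precision and weighted recall, each as
mean +/- SD over train and test sides of the MCCV; any train-minus-test gap
above 0.1 is flagged as overfitting.

Forest hyperparameters default to 500 trees, sqrt-features per split,
unlimited depth and inverse-frequency case weights, with one derived seed
per MCCV iteration; stratified splits are used because the subtype sizes
are unequal and an unstratified 20% test set can lose a class.

## The synthetic cohort generator

`generate_cohort()` draws the cohort the analyses are tested against: 333
patients in four latent subtypes with proportions 16/98/103/116 and graded
latent severity; ~600 proteins with per-protein log2 baselines N(20, 2),
Gaussian residual SD 0.5 and additive subtype shifts organised in four
signature blocks (immunoglobulin 100, acute-phase 60, cytosolic 60,
adhesion 50, remainder null); day-4 samples for 213/333 patients re-drawn
around the day-4 subtype mean after a mostly-diagonal migration step; MNAR
missingness with a per-cell Bernoulli logit linear in intensity, calibrated
by root finding to a 20% marginal rate; severity-linked SOFA-, lactate- and
creatinine-like variables plus null clinical variables; IgG/IgA/IgM
concentrations high in subtype 1 and lowest in subtype 2; and Bernoulli
30-day mortality with a logit linear in severity (intercept -1.13, slope
0.61), giving ~100% mortality in subtype 0, ~30-45% elsewhere and ~39%
overall. Death days are uniform on 1-14 for subtype 0 and 1-30 otherwise,
mimicking the much shorter survival of the moribund subtype without
fitting it.

The block design gives each subtype pair a balanced number of
distinguishing proteins rather than a few large effects. This matters
because z-standardization bounds the per-protein contrast: a protein's
marginal SD grows with its between-subtype variance, so raising
`effect_size` saturates, and what controls the cluster geometry is how
*many* proteins separate a pair. With the default design (signal fraction
~45% of proteins) the four subtypes are mutually separated by at least one
within-cluster radius in z-space, and all three cluster-count diagnostics
prefer k = 4; with `effect_size = 0` the gap rule correctly prefers k = 1.

The generator declares its simplifications: no batch effects or
mass-spectral structure, per-cell (not per-run) missingness, no
within-patient autocorrelation beyond the subtype migration, categorical
clinical variables independent of subtype, and independent Gaussian
residuals. Passing tests therefore demonstrate correctness of the
procedures under these assumptions, not robustness to batch artefacts or
correlated noise in real plasma data.

`simulate_feature_cohort()` builds the planted-truth cohorts for the
classifier checks: exactly `s` signal proteins carrying complementary class
contrasts (one-vs-rest, pairwise and one-vs-mean patterns in rotation) with
a per-protein effect of `effect / sqrt(s)`. The budget scaling reflects a
three-class limitation: class-boundary information saturates, so a panel of
more markers must consist of individually weaker ones for the recall curve
to keep growing until the full set is included — which is exactly the
regime in which a knee at the panel size exists and knee-point sizing is
the right tool. With `grade < 1` the effects decrease linearly, planting a
recoverable importance ordering for the ranking tests. Knee-recovery checks
scan the protein grid to about four times the planted size, in line with
scanning ~40 candidates for a ~10-protein panel.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step consumes seeds from `derive_seeds(master,
  n, salt)` — distinct salts per consumer, all below 2^31; no hidden global
  RNG state is touched (the caller's `.Random.seed` is saved and restored).
* Zero-variance proteins abort standardization with the protein named;
  all-missing proteins abort imputation likewise.
* Exact assignment-distance ties go to the lowest severity-ordered label;
  k-means runs that empty a cluster are re-seeded up to 20 times.
* Constant columns have undefined correlations and are retained by the
  pruner with a warning; constant profiles abort pattern clustering.
* All-tied Kruskal-Wallis input returns p = 1 with a degenerate flag;
  Bonferroni products are capped at 1; zero-margin contingency rows or
  columns are dropped with a warning.
* Fisher's test on tables larger than 2x3 falls back to Monte Carlo
  p-values (1e5 draws) to bound memory.
* The null-safety check of the significance gate uses ground-truth labels:
  with zero effect size, labels re-derived from the data are circular and
  FDR calibration claims only apply to labels independent of the
  intensities.

## Problem sizes used by the tests

The bundled checks run on reduced but structurally faithful cohorts chosen
as the smallest sizes at which the studied effects are comfortably
resolved: 400 patients x 300 proteins for cluster-count and
parameter-recovery checks (10 seeds), 200 x 200 for null-safety (10 seeds),
and 300 patients with s + 20 protein candidates for the panel-recovery
checks (10 seeds per planted size, 25 MCCV iterations per grid cell,
100-tree forests). The analysis scripts under `analysis/` run the full
default cohort (333 x 600) with 100 MCCV iterations and 500-tree forests.

## Known limitations

* Ward linkage on correlation dissimilarities is formally improper (see
  above); it is retained by design.
* The gap statistic uses the bounding-box uniform reference; the
  PCA-aligned reference variant is not implemented.
* SHAP attributions use the path-dependent cover weighting, which is known
  to distribute credit among correlated features differently from the
  interventional variant; with pruning at |r| > 0.7 upstream the practical
  difference is small.
* The generator's missingness is MNAR per cell; block-dropout or
  run-level missingness patterns of real DIA data are not emulated — the
  true missingness mechanism of DIA plasma data is not established, and the
  MNAR slope is a free parameter, not a claim about any particular study.
* No consensus clustering, alternative clusterers, moderated-variance
  models, survival regression or enrichment analysis: out of scope.
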