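# sepsubtype

Sepsis is a heterogeneous syndrome: clinically similar patients can carry
very different molecular states, which is a leading explanation for why
mechanism-targeted sepsis trials keep failing. One way to resolve this
heterogeneity is to subtype patients directly on their plasma proteome.
`sepsubtype` implements such an analysis end to end, for researchers
working with DIA plasma proteomics of ICU cohorts:

* **Subtype discovery** on day-1 protein intensities: completeness
  filtering (< 30% missing at both timepoints), per-matrix median
  imputation, per-protein z-standardization, PCA truncated at > 70%
  cumulative variance, and k-means (k-means++/Lloyd, 25 restarts) with
  silhouette, gap-statistic and Davies-Bouldin cluster-count diagnostics.
  Clusters are relabelled 0..k-1 by decreasing median SOFA score, so label
  0 is always the most severe subtype.
* **Longitudinal projection**: day-4 samples are standardized, projected
  and assigned to the nearest centroid using the *frozen* day-1 parameters
  (never refit), giving per-patient subtype trajectories.
* **Differential abundance** per protein: one-way ANOVA with
  Benjamini-Hochberg correction, Tukey's post-hoc test, linear-scale
  ratios of means (RoM), and the three-condition significance gate
  p_FDR <= 0.05 AND pair p <= 0.05 AND (RoM >= 1.5 OR RoM <= 0.67),
  followed by abundance-pattern clustering (1 - Pearson dissimilarity,
  Ward linkage).
* **Clinical statistics**: registered-rule aggregation (median/min/max),
  median/IQR summaries, Kruskal-Wallis + Bonferroni-corrected Dunn
  post-hoc tests, chi-square/Fisher contingency tests, Kaplan-Meier
  30-day survival.
* **Minimal-panel classifier** for subtypes 1-3: immunoglobulin protein
  entries are replaced by routine IgG/IgA/IgM concentrations,
  routine-assay proteins excluded, features pruned at |r| > 0.7, ranked by
  median SHAP rank over Monte Carlo cross-validation (path-dependent
  TreeSHAP, implemented in C++), scanned by a nested medical x protein
  feature-count grid, sized by Kneedle knee-point detection on the
  proteins-only recall curve, and evaluated by stratified 80/20 MCCV
  (accuracy, macro AUROC, weighted F1, multiclass MCC, precision, recall).
* **A synthetic-cohort generator** that emulates the statistical structure
  of a multicentre sepsis cohort (333 patients, four subtypes of graded
  severity with proportions 16/98/103/116, signature protein blocks,
  MNAR missingness, day-4 follow-up with subtype migration, severity-linked
  clinical variables, ~40% 30-day mortality), so the entire pipeline is
  testable without access to patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a generated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_subtype_discovery.R 1
Rscript analysis/03_differential_abundance.R
Rscript analysis/04_clinical_characterization.R
Rscript analysis/05_classifier_panel.R 1 25 100   # seed, MCCV iterations, trees
```

which prints:

```
cohort: 333 patients day 1, 213 day 4, 600 proteins
day-1 missingness: 20.0%; 30-day mortality: 37.5%
subtype sizes: 16 / 98 / 103 / 116
completeness filter kept 442 proteins; 73 PCs cover 70.2% variance
cluster-count diagnostics: silhouette -> 4, Davies-Bouldin -> 4, gap -> 4
day-4 assignment: 77% of followed patients stay in their subtype
significantly differential proteins: 193 at day 1, 193 at day 4 (of 442 tested)
day-1 abundance-pattern sizes: 59 / 44 / 43 / 29 / 18
SOFA separates the subtypes: Kruskal-Wallis p = 3.13e-29
median SOFA by subtype: 15.5 / 10 / 8 / 7
30-day mortality by subtype: 100% / 41% / 23% / 39%
...
top-ranked proteins: SAA1 GPT CYT020 CYT016 CYT040 ICAM1 CYT030 GOT1 CYT029 LDHA
knee of the proteins-only recall curve: 6 proteins
final panel: SAA1 CYT020 GPT CYT016 CYT040 ICAM1 IgG IgA IgM
     metric test_mean  test_sd train_mean train_sd      gap
1  accuracy     0.975 0.014264          1        0 0.025000
2     auroc     0.999 0.000902          1        0 0.000803
...
```

Reading the output: the four generated subtypes are recovered exactly
(all three cluster-count diagnostics point at k = 4, and the median SOFA
gradient 15.5 / 10 / 8 / 7 reproduces the severity ordering the labels are
named by); 193 of 442 testable proteins pass the three-condition
significance gate at day 1 and fall into five abundance patterns; and the
knee-sized biomarker panel (six proteins — acute-phase and
cytosolic-leakage markers plus ICAM1 — with the three immunoglobulin
concentrations) classifies subtypes 1-3 with test AUROC 0.999 and MCC 0.96
on this synthetic cohort. Real-data performance is necessarily lower; the
generator's assumptions are documented in the methods vignette
(`vignettes/sepsis-proteome-subtyping.Rmd`).

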