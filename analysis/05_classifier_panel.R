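#!/usr/bin/env Rscript
# Minimal-panel random-forest classifier for subtypes 1-3: feature-table
# assembly (immunoglobulin proteins replaced by IgG/IgA/IgM concentrations,
# routine-assay proteins excluded, correlation pruning at |r| > 0.7,
# Kruskal-Wallis filter on clinical features), SHAP-ranked nested MCCV
# feature selection, knee-point panel sizing on the proteins-only recall
# curve, and final-panel evaluation (accuracy, macro AUROC, weighted F1,
# multiclass MCC, precision, recall) by stratified 80/20 MCCV.

library(sepsubtype)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
n_mccv <- if (length(args) > 1) as.integer(args[2]) else 100L
num_trees <- if (length(args) > 2) as.integer(args[3]) else 500L

day1 <- read_intensity_tsv("data/cohort/day1.tsv")
clinical <- sepsubtype:::read_tsv_schema("data/cohort/clinical.tsv")
registry <- sepsubtype:::read_tsv_schema("data/cohort/registry.tsv")
ig <- sepsubtype:::read_tsv_schema("data/cohort/ig.tsv")
lab1 <- sepsubtype:::read_tsv_schema("results/labels_day1.tsv")
labels1 <- setNames(lab1$label, lab1$patient_id)

wide <- aggregate_daily(clinical, registry, fill_days = 2L)
ft <- build_feature_table(day1, wide, ig, labels1)
print(ft)

ranks <- shap_rank(ft, n_mccv = n_mccv, seed = seed, num_trees = num_trees)
cat("top-ranked proteins:", head(ranks$order$protein, 10), "\n")

trace <- nested_selection(ft, ranks, grid_medical = 0:3, grid_protein = 1:25,
                          n_mccv = n_mccv, seed = seed + 1L, num_trees = num_trees)
prot_curve <- trace$surface[trace$surface$n_medical == 0, ]
knee <- knee_point(prot_curve$n_protein, prot_curve$recall_mean)
cat(sprintf("knee of the proteins-only recall curve: %s proteins\n", knee))

panel <- finalize_panel(trace, if (is.na(knee)) max(prot_curve$n_protein) else knee)
cat("final panel:", panel$panel, "\n")

pm <- train_evaluate(ft, panel$panel, n_mccv = n_mccv, seed = seed + 2L, num_trees = num_trees)
print(pm)

dir.create("results/trace", showWarnings = FALSE, recursive = TRUE)
sepsubtype:::write_tsv_schema(trace$surface, "results/trace/recall_surface.tsv",
                              "sepsubtype-trace-v1")
sepsubtype:::write_tsv_schema(panel$selection_freq,
                              "results/trace/selection_freq.tsv",
                              "sepsubtype-trace-v1")
sepsubtype:::write_tsv_schema(pm$metrics, "results/metrics.tsv",
                              "sepsubtype-metrics-v1")
jsonlite::write_json(list(schema = "sepsubtype-panel-v1",
                          knee = knee, panel = pm$panel,
                          overfitting = pm$overfitting),
                     "results/panel.json", auto_unbox = TRUE, digits = NA)
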