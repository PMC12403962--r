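#!/usr/bin/env Rscript
# Day-1 subtype discovery and day-4 projection: completeness filter, median
# imputation, z-standardization, PCA (>70% variance), cluster-count
# diagnostics (silhouette, gap statistic, Davies-Bouldin), k-means with k=4,
# severity-ordered relabelling, frozen-parameter day-4 assignment and
# trajectory tabulation.

library(sepsubtype)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

day1 <- read_intensity_tsv("data/cohort/day1.tsv")
day4 <- read_intensity_tsv("data/cohort/day4.tsv")
clinical <- sepsubtype:::read_tsv_schema("data/cohort/clinical.tsv")
registry <- sepsubtype:::read_tsv_schema("data/cohort/registry.tsv")
truth <- sepsubtype:::read_tsv_schema("data/cohort/truth.tsv")

wide <- aggregate_daily(clinical, registry)
sofa <- setNames(wide$sofa, wide$patient_id)

model <- fit_subtype_model(day1, day4, sofa, k = 4L, seed = seed)
cat(sprintf("completeness filter kept %d proteins; %d PCs cover %.1f%% variance\n",
            length(model$protein_ids), model$basis$m, 100 * model$basis$cum_var))

z1 <- apply_standardizer(impute_median(subset_proteins(day1, model$protein_ids)),
                         model$params)
scores <- project_pca(z1, model$basis)
diag_tab <- choose_k(scores, 2:8, B_reference = 50L, seed = seed + 1L)
sug <- attr(diag_tab, "suggested")
cat(sprintf("cluster-count diagnostics: silhouette -> %d, Davies-Bouldin -> %d, gap -> %d\n",
            sug$silhouette, sug$davies_bouldin, sug$gap))

labels4 <- assign_matrix(day4, model)
dead30 <- setNames(as.logical(truth$dead30), truth$patient_id)
traj <- trajectories(model$labels_day1, labels4, dead30)
stay <- sum(traj$n[traj$day1 == traj$day4]) / sum(traj$n)
cat(sprintf("day-4 assignment: %.0f%% of followed patients stay in their subtype\n",
            100 * stay))

dir.create("results", showWarnings = FALSE)
write_subtype_model(model, "results/model.json")
sepsubtype:::write_tsv_schema(diag_tab, "results/k_diagnostics.tsv",
                              "sepsubtype-diagnostics-v1")
sepsubtype:::write_tsv_schema(
  data.frame(patient_id = names(model$labels_day1), label = model$labels_day1),
  "results/labels_day1.tsv", "sepsubtype-labels-v1")
sepsubtype:::write_tsv_schema(
  data.frame(patient_id = names(labels4), label = labels4),
  "results/labels_day4.tsv", "sepsubtype-labels-v1")
sepsubtype:::write_tsv_schema(traj, "results/trajectories.tsv",
                              "sepsubtype-trajectories-v1")
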