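#!/usr/bin/env Rscript
# Per-protein differential abundance between the subtypes at each timepoint:
# one-way ANOVA with Benjamini-Hochberg correction, Tukey's post-hoc test,
# linear-scale ratios of means, the three-condition significance gate
# (p_FDR <= 0.05, pair p <= 0.05, RoM >= 1.5 or <= 0.67) and
# abundance-pattern clustering (Pearson dissimilarity, Ward linkage; five
# branches at day 1, four at day 4).

library(sepsubtype)

day1 <- read_intensity_tsv("data/cohort/day1.tsv")
day4 <- read_intensity_tsv("data/cohort/day4.tsv")
model <- read_subtype_model("results/model.json")
lab1 <- sepsubtype:::read_tsv_schema("results/labels_day1.tsv")
lab4 <- sepsubtype:::read_tsv_schema("results/labels_day4.tsv")
labels1 <- setNames(lab1$label, lab1$patient_id)
labels4 <- setNames(lab4$label, lab4$patient_id)

d1 <- impute_median(subset_proteins(day1, model$protein_ids))
d4 <- impute_median(subset_proteins(day4, model$protein_ids))

diff1 <- diff_abundance(d1, labels1[d1$samples$patient_id], n_branches = 5L)
diff4 <- diff_abundance(d4, labels4[d4$samples$patient_id], n_branches = 4L)

cat(sprintf("significantly differential proteins: %d at day 1, %d at day 4 (of %d tested)\n",
            sum(diff1$significant), sum(diff4$significant), sum(diff1$testable)))
cat("day-1 abundance-pattern sizes:",
    paste(table(diff1$pattern), collapse = " / "), "\n")

sepsubtype:::write_tsv_schema(diff1, "results/diff_day1.tsv", "sepsubtype-diff-v1")
sepsubtype:::write_tsv_schema(diff4, "results/diff_day4.tsv", "sepsubtype-diff-v1")
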