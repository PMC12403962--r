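#!/usr/bin/env Rscript
# Clinical characterization of the subtypes: per-cluster summaries
# (median/IQR, counts/percent), Kruskal-Wallis + Bonferroni-corrected Dunn
# post-hoc tests for numeric variables, chi-square/Fisher tests for
# categorical variables, and Kaplan-Meier 30-day survival per subtype.

library(sepsubtype)

clinical <- sepsubtype:::read_tsv_schema("data/cohort/clinical.tsv")
registry <- sepsubtype:::read_tsv_schema("data/cohort/registry.tsv")
truth <- sepsubtype:::read_tsv_schema("data/cohort/truth.tsv")
lab1 <- sepsubtype:::read_tsv_schema("results/labels_day1.tsv")
labels1 <- setNames(lab1$label, lab1$patient_id)

wide <- aggregate_daily(clinical, registry)
tab1 <- clinical_summary_table(wide, registry, labels1)
sepsubtype:::write_tsv_schema(tab1, "results/table1.tsv", "sepsubtype-table1-v1")

sofa_omni <- tab1$omnibus_p[tab1$variable == "sofa"][1]
cat(sprintf("SOFA separates the subtypes: Kruskal-Wallis p = %.2e\n", sofa_omni))
med_sofa <- summarize_by_cluster(wide$sofa, labels1[wide$patient_id])
cat("median SOFA by subtype:", paste(med_sofa$median, collapse = " / "), "\n")

times <- ifelse(as.logical(truth$dead30), truth$death_day, 30)
km <- km_curve(times, as.logical(truth$dead30), labels1[truth$patient_id])
sepsubtype:::write_tsv_schema(km$curves, "results/km.tsv", "sepsubtype-km-v1")
sepsubtype:::write_tsv_schema(km$death_day_summary,
                              "results/survival_time.tsv", "sepsubtype-km-v1")
mort <- tapply(as.logical(truth$dead30), labels1[truth$patient_id], mean)
cat("30-day mortality by subtype:",
    paste(sprintf("%.0f%%", 100 * mort), collapse = " / "), "\n")
cat("median death day (deceased only):",
    paste(km$death_day_summary$median, collapse = " / "), "\n")
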