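test_that("two-group ANOVA reduces to the squared pooled t-test", {
  set.seed(31)
  v <- matrix(rnorm(40), 2)
  labels <- rep(0:1, each = 10)
  an <- anova_per_protein(toy_matrix(v), labels)
  for (i in 1:2) {
    tt <- t.test(v[i, labels == 0], v[i, labels == 1], var.equal = TRUE)
    expect_equal(an$F[i], unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(an$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("three-group ANOVA matches a textbook sum-of-squares computation", {
  v <- c(4.1, 5.0, 4.4, 6.2, 7.1, 6.6, 5.0, 5.2, 4.6, 5.4)
  labels <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 2)
  an <- anova_per_protein(toy_matrix(matrix(v, 1)), labels)
  grand <- mean(v)
  ssb <- sum(tapply(v, labels, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(v, labels, function(g) sum((g - mean(g))^2)))
  F_oracle <- (ssb / 2) / (ssw / 7)
  expect_equal(an$F[1], F_oracle, tolerance = 1e-12)
  expect_equal(an$p[1], pf(F_oracle, 2, 7, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("proteins with undersized or degenerate groups are untestable", {
  v <- rbind(c(1, 2, 3, 4, 9), c(1, 1, 2, 2, 3))
  labels <- c(0, 0, 1, 1, 2)  # group 2 has one sample
  an <- anova_per_protein(toy_matrix(v), labels)
  expect_false(any(an$testable))
  v2 <- rbind(c(1, 1.2, 2, 2.1), c(1, 1, 1, 1))
  an2 <- anova_per_protein(toy_matrix(v2), c(0, 0, 1, 1))
  expect_true(an2$testable[1])
  expect_false(an2$testable[2])  # zero within-group variance
  # untestable proteins are excluded from the FDR denominator
  p <- c(0.02, NA)
  expect_equal(bh_adjust(p)[1], 0.02)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(32)
  p <- runif(200)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
})

test_that("Tukey's test reduces to the pooled t-test for two groups", {
  set.seed(33)
  v <- matrix(rnorm(30), 2)
  labels <- rep(0:1, c(7, 8))
  tk <- tukey_posthoc(toy_matrix(v), labels)
  for (i in 1:2) {
    tt <- t.test(v[i, labels == 0], v[i, labels == 1], var.equal = TRUE)
    q <- sqrt(2) * abs(tt$statistic)
    p_oracle <- ptukey(q, nmeans = 2, df = 13, lower.tail = FALSE)
    expect_equal(tk$p_0_1[i], unname(p_oracle), tolerance = 1e-9)
  }
})

test_that("identical groups give Tukey p near one, a shifted group stands out", {
  set.seed(34)
  base <- rnorm(24, sd = 0.2)
  v <- matrix(base, 1)
  labels <- rep(0:2, each = 8)
  tk_null <- tukey_posthoc(toy_matrix(matrix(rep(c(1, 2, 3, 4), 6), 1)),
                           rep(0:2, each = 8))
  expect_true(all(tk_null[1, -1] > 0.9))
  v[1, labels == 2] <- v[1, labels == 2] + 3
  tk <- tukey_posthoc(toy_matrix(v), labels)
  expect_gt(tk$p_0_1[1], 0.05)
  expect_lt(tk$p_0_2[1], 0.001)
  expect_lt(tk$p_1_2[1], 0.001)
})

test_that("ratios of means are linear-scale with the lower label on top", {
  v <- matrix(log2(c(3, 3, 2, 2)), 1)
  rom <- ratio_of_means(toy_matrix(v), c(0, 0, 1, 1))
  expect_equal(rom$rom_0_1[1], 1.5)
  rom2 <- ratio_of_means(toy_matrix(matrix(log2(c(2, 2, 3, 3)), 1)),
                         c(0, 0, 1, 1))
  expect_equal(rom2$rom_0_1[1], 2 / 3)
  expect_lte(rom2$rom_0_1[1], 0.67)
  rom3 <- ratio_of_means(toy_matrix(matrix(1, 1, 4)), c(0, 0, 1, 1))
  expect_equal(rom3$rom_0_1[1], 1)
})

test_that("the significance gate demands all three conditions on one pair", {
  tukey <- data.frame(protein_id = c("a", "b", "c"),
                      p_0_1 = c(0.04, 0.04, 0.2))
  rom <- data.frame(protein_id = c("a", "b", "c"),
                    rom_0_1 = c(1.6, 1.4, 2.0))
  g <- significance_gate(c(0.04, 0.04, 0.01), tukey, rom)
  expect_equal(g$significant, c(TRUE, FALSE, FALSE))
})

test_that("gate flags equal an independent boolean recomputation", {
  co <- generate_cohort(cohort_config(
    n_patients = 120L, n_proteins = 50L,
    block_sizes = c(immunoglobulin = 10L, acute_phase = 8L,
                    cytosolic = 8L, adhesion = 6L),
    seed = 35L))
  x <- impute_median(co$day1)
  labels <- co$truth$subtype_day1[match(x$samples$patient_id,
                                        co$truth$patient_id)]
  an <- anova_per_protein(x, labels)
  p_fdr <- bh_adjust(an$p)
  tk <- tukey_posthoc(x, labels)
  rm_ <- ratio_of_means(x, labels)
  g <- significance_gate(p_fdr, tk, rm_)
  pair_tags <- sub("^p_", "", names(tk)[-1])
  oracle <- rep(FALSE, nrow(tk))
  for (tag in pair_tags) {
    ok <- !is.na(p_fdr) & p_fdr <= 0.05 &
      !is.na(tk[[paste0("p_", tag)]]) & tk[[paste0("p_", tag)]] <= 0.05 &
      (rm_[[paste0("rom_", tag)]] >= 1.5 | rm_[[paste0("rom_", tag)]] <= 0.67)
    expect_equal(g[[paste0("sig_", tag)]], ok)
    oracle <- oracle | ok
  }
  expect_equal(g$significant, oracle)
})

test_that("gate counts are monotone in each threshold", {
  co <- generate_cohort(cohort_config(
    n_patients = 120L, n_proteins = 60L,
    block_sizes = c(immunoglobulin = 12L, acute_phase = 10L,
                    cytosolic = 8L, adhesion = 6L),
    seed = 36L))
  x <- impute_median(co$day1)
  labels <- co$truth$subtype_day1[match(x$samples$patient_id,
                                        co$truth$patient_id)]
  an <- anova_per_protein(x, labels)
  p_fdr <- bh_adjust(an$p)
  tk <- tukey_posthoc(x, labels)
  rm_ <- ratio_of_means(x, labels)
  n_sig <- function(...) sum(significance_gate(p_fdr, tk, rm_, ...)$significant)
  base <- n_sig()
  expect_gte(n_sig(p_fdr_max = 0.1), base)
  expect_gte(n_sig(p_pair_max = 0.1), base)
  expect_gte(n_sig(rom_up = 1.3, rom_down = 0.77), base)
})

test_that("abundance patterns separate anticorrelated groups and duplicates", {
  prof <- rbind(matrix(rep(c(1, 0, -1, 0), 4), 4, byrow = TRUE),
                matrix(rep(c(-1, 0, 1, 0), 3), 3, byrow = TRUE))
  prof <- prof + matrix(rnorm(28, sd = 0.01), 7)
  rownames(prof) <- sprintf("PR%02d", 1:7)
  pat <- abundance_patterns(prof, 2L)
  expect_equal(length(unique(pat[1:4])), 1L)
  expect_equal(length(unique(pat[5:7])), 1L)
  expect_false(pat[1] == pat[5])
  expect_equal(unname(pat[1]), 1L)  # larger branch labelled 1
})

test_that("pattern clustering follows the Lance-Williams Ward update", {
  set.seed(37)
  prof <- matrix(rnorm(32), 8, dimnames = list(sprintf("PR%02d", 1:8), NULL))
  got <- abundance_patterns(prof, 3L)
  D <- as.matrix(1 - cor(t(prof)))
  oracle <- ward_lw_oracle(D, 3L)
  # same partition up to label names
  expect_equal(length(unique(paste(got, oracle))), 3L)
  expect_error(abundance_patterns(rbind(prof, PRX = rep(1, 4)), 3L), "PRX")
})

test_that("signal-block proteins dominate the significant calls", {
  co <- small_cohort(seed = 38L)
  x <- impute_median(co$day1)
  labels <- co$truth$subtype_day1[match(x$samples$patient_id,
                                        co$truth$patient_id)]
  res <- diff_abundance(x, labels)
  is_null_block <- grepl("^PLS", co$day1$proteins$gene)
  tab <- table(signal = !is_null_block, sig = res$significant)
  p <- fisher.test(tab, alternative = "greater")$p.value
  expect_lt(p, 0.01)
  # significant proteins get pattern labels, others NA
  expect_true(all(!is.na(res$pattern[res$significant])))
  expect_true(all(is.na(res$pattern[!res$significant])))
})
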