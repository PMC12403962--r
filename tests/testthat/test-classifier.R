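as_ft <- function(fc) fc  # simulate_feature_cohort already is a feature_table

test_that("correlation pruning follows the greedy strict-threshold rule", {
  pair <- exact_cor_pair(60, 0.69)
  expect_equal(correlation_prune(pair, 0.7), c("x", "y"))  # strict >
  pair2 <- exact_cor_pair(60, 0.71)
  expect_equal(correlation_prune(pair2, 0.7), "x")
  pair3 <- exact_cor_pair(60, -0.8)
  expect_equal(correlation_prune(pair3, 0.7), "x")  # absolute value
})

test_that("pruning a correlation chain keeps the endpoints", {
  set.seed(51)
  n <- 400
  # build exact-geometry columns from an orthonormal empirical basis:
  # cor(A,B) = 0.9, cor(B,C) = 0.75, cor(A,C) = 0.45
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  Q <- scale(Q) / sqrt(1 - 1 / n)  # unit sample variance, orthogonal
  a <- Q[, 1]
  b <- 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2]
  r_ac <- 0.45
  c2 <- (0.75 - r_ac * 0.9) / sqrt(1 - 0.81)
  cc <- r_ac * Q[, 1] + c2 * Q[, 2] + sqrt(1 - r_ac^2 - c2^2) * Q[, 3]
  X <- cbind(A = a, B = b, C = cc)
  stopifnot(abs(cor(X)["A", "B"]) > 0.7, abs(cor(X)["B", "C"]) > 0.7,
            abs(cor(X)["A", "C"]) < 0.7)
  expect_equal(correlation_prune(X, 0.7), c("A", "C"))
  # duplicated column: first in input order wins
  dup <- cbind(P1 = a, P2 = a)
  expect_equal(correlation_prune(dup, 0.7), "P1")
  expect_warning(correlation_prune(cbind(K = rep(1, 10), L = rnorm(10))),
                 "constant")
})

test_that("feature table applies exclusions, replacements and filters", {
  co <- small_cohort(seed = 52L)
  wide <- aggregate_daily(co$clinical, co$registry)
  labels <- setNames(co$truth$subtype_day1, co$truth$patient_id)
  ft <- build_feature_table(co$day1, wide, co$ig, labels)
  feats <- names(ft$table)
  expect_false(any(grepl("^IGH|^IGK|^IGL|^JCHAIN", feats)))
  expect_false(any(c("CRP", "FGA", "FGB", "FGG", "HBA2", "HBB", "HBD") %in% feats))
  expect_true(all(c("IgG", "IgA", "IgM") %in% feats))
  expect_false(any(ft$table$label == 0))
  # no residual high correlation among retained columns
  M <- as.matrix(ft$table[, c(ft$ig_cols, ft$protein_cols, ft$medical_cols)])
  cm <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  expect_lte(max(abs(cm), na.rm = TRUE), 0.7 + 1e-12)
  # clinical features all separate the subtypes
  for (v in ft$medical_cols)
    expect_lt(kruskal_wallis(ft$table[[v]], ft$table$label)$p, 0.05)
  expect_false(any(colMeans(is.na(ft$table[, -(1:2)])) > 0.30))
  # missing Ig concentrations abort
  ig_bad <- co$ig
  ig_bad$IgG[seq_len(ceiling(0.4 * nrow(ig_bad)))] <- NA
  expect_error(build_feature_table(co$day1, wide, ig_bad, labels),
               "immunoglobulin")
})

test_that("exported forests reproduce ranger predictions exactly", {
  set.seed(53)
  X <- matrix(rnorm(300), 100, dimnames = list(NULL, paste0("f", 1:3)))
  y <- factor(ifelse(X[, 1] - X[, 2] + rnorm(100, 0, 0.4) > 0, "a", "b"))
  rf <- sepsubtype:::fit_forest(X, y, num_trees = 30L, seed = 5L)
  fx <- sepsubtype:::export_forest(rf, X)
  pred_cpp <- sepsubtype:::cpp_forest_predict(fx, X)
  pred_rg <- predict(rf, data = as.data.frame(X), num.threads = 1)$predictions
  expect_equal(max(abs(pred_cpp - unname(pred_rg))), 0)
})

test_that("TreeSHAP equals brute-force Shapley values on small forests", {
  set.seed(54)
  p <- 4
  X <- matrix(rnorm(60 * p), 60, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(60, 0, 0.5) > 0, "a", "b"))
  rf <- sepsubtype:::fit_forest(X, y, num_trees = 10L, seed = 2L)
  fx <- sepsubtype:::export_forest(rf, X)
  sh <- forest_shap(rf, X, X[1:4, , drop = FALSE])
  for (s in 1:4) {
    bf <- Reduce(`+`, lapply(fx, function(tr)
      brute_shapley_oracle(tr, X[s, ], p))) / length(fx)
    expect_lt(max(abs(sh[s, , ] - bf)), 1e-10)
  }
  # additivity: baseline + sum of attributions = prediction
  base <- Reduce(`+`, lapply(fx, function(tr)
    tree_expvalue(tr, X[1, ], integer(0)))) / length(fx)
  pred <- sepsubtype:::cpp_forest_predict(fx, X[1, , drop = FALSE])
  expect_lt(max(abs(base + colSums(sh[1, , ]) - pred[1, ])), 1e-10)
})

test_that("a label-determining feature earns median rank one", {
  set.seed(55)
  n <- 120
  cls <- rep(1:3, each = n / 3)
  prot <- matrix(rnorm(n * 5), n,
                 dimnames = list(NULL, paste0("P", 1:5)))
  prot[, 3] <- cls * 4 + rnorm(n, 0, 0.1)
  tab <- data.frame(patient_id = sprintf("x%03d", 1:n), label = cls, prot,
                    med_01 = rnorm(n),
                    IgG = rnorm(n), IgA = rnorm(n), IgM = rnorm(n))
  ft <- structure(list(table = tab, protein_cols = paste0("P", 1:5),
                       medical_cols = "med_01",
                       ig_cols = c("IgG", "IgA", "IgM")),
                  class = "feature_table")
  r <- suppressWarnings(shap_rank(ft, n_mccv = 5L, seed = 1L, num_trees = 60L))
  expect_equal(unname(r$median_rank$protein["P3"]), 1)
  r2 <- suppressWarnings(shap_rank(ft, n_mccv = 2L, seed = 9L, num_trees = 30L))
  r3 <- suppressWarnings(shap_rank(ft, n_mccv = 2L, seed = 9L, num_trees = 30L))
  expect_identical(r2$rank_iter, r3$rank_iter)
})

test_that("median SHAP ranks recover a planted effect-size ordering", {
  sp <- vapply(1:2, function(s) {
    fc <- simulate_feature_cohort(n_per_class = 100L, s_signal = 5L,
                                  grade = 0.5, effect = 4.5, seed = s)
    r <- shap_rank(fc, n_mccv = 12L, seed = s, num_trees = 100L)
    mr <- r$median_rank$protein[fc$signal_proteins]
    cor(seq_along(mr), mr, method = "spearman")
  }, numeric(1))
  expect_true(all(sp >= 0.8))
})

test_that("a single-iteration selection scan equals a directly scripted split", {
  fc <- simulate_feature_cohort(n_per_class = 40L, s_signal = 3L,
                                n_noise = 5L, seed = 6L)
  ranks <- shap_rank(fc, n_mccv = 4L, seed = 2L, num_trees = 40L)
  tr <- nested_selection(fc, ranks, grid_medical = 0L, grid_protein = 2L,
                         n_mccv = 1L, seed = 3L, num_trees = 40L)
  # script the same single split by hand
  y <- factor(fc$table$label)
  cols <- c(fc$ig_cols, ranks$order$protein[1:2])
  seeds <- derive_seeds(3L, 1L, salt = 57L)
  rec_oracle <- sepsubtype:::with_seed(seeds[1], {
    tr_idx <- sepsubtype:::stratified_split(y, 0.8)
    X <- as.matrix(fc$table[, cols])
    rf <- sepsubtype:::fit_forest(X[tr_idx, ], y[tr_idx], 40L, seed = seeds[1])
    pred <- predict(rf, data = as.data.frame(X[-tr_idx, , drop = FALSE]),
                    num.threads = 1)$predictions
    cls <- factor(colnames(pred)[max.col(pred, ties.method = "first")],
                  levels = levels(y))
    confusion_metrics(y[-tr_idx], cls)$recall_weighted
  })
  expect_equal(tr$surface$recall_mean, rec_oracle)
})

test_that("knee-point detection follows the normalized difference curve", {
  expect_true(is.na(knee_point(1:10, 1:10)))             # linear: no knee
  expect_true(is.na(knee_point(1:5, rep(0.5, 5))))       # flat
  expect_true(is.na(knee_point(1:6, 6:1)))               # decreasing
  y <- c(0.2, 0.5, 0.7, 0.8, 0.805, 0.81, 0.81)  # steep to x = 3, then flat
  expect_equal(knee_point(1:7, y), 3)
  expect_equal(knee_point(1:7, y * 10), 3)               # scale invariance
  expect_equal(knee_point(1:7, y), kneedle_oracle(1:7, y))
  set.seed(57)
  for (i in 1:20) {
    yy <- sort(runif(8))
    expect_identical(knee_point(1:8, yy), kneedle_oracle(1:8, yy))
  }
  expect_error(knee_point(1:3, 1:3))
})

test_that("panel finalization ranks by frequency with median-rank tie-breaks", {
  ri <- rbind(A = c(1, 2, 1, 1), B = c(2, 1, 3, 2),
              C = c(3, 3, 2, 3), D = c(4, 4, 4, 4))
  ranks <- structure(list(median_rank = list(protein = c(A = 1, B = 2, C = 3, D = 4)),
                          rank_iter = list(protein = ri)),
                     class = "selection_ranks")
  pan <- finalize_panel(ranks, 2)
  expect_equal(pan$proteins, c("A", "B"))
  expect_equal(pan$panel, c("A", "B", "IgG", "IgA", "IgM"))
  # tie in frequency: C and B appear equally often in top-3; median rank wins
  pan3 <- finalize_panel(ranks, 3)
  expect_equal(pan3$proteins, c("A", "B", "C"))
})

test_that("confusion metrics match hand-tallied values on a 3x3 fixture", {
  truth <- factor(rep(c("a", "b", "c"), c(10, 8, 6)))
  pred <- factor(c(rep("a", 8), "b", "c",      # a: 8 right
                   rep("b", 6), "a", "c",      # b: 6 right
                   rep("c", 5), "a"),          # c: 5 right
                 levels = c("a", "b", "c"))
  cm <- confusion_metrics(truth, pred)
  expect_equal(cm$accuracy, 19 / 24)
  prec <- c(8 / 10, 6 / 7, 5 / 7)
  rec <- c(8 / 10, 6 / 8, 5 / 6)
  w <- c(10, 8, 6) / 24
  expect_equal(cm$precision_weighted, sum(w * prec))
  expect_equal(cm$recall_weighted, sum(w * rec))
  expect_equal(cm$f1_weighted, sum(w * 2 * prec * rec / (prec + rec)))
  # Gorodkin MCC equals one-hot Pearson correlation
  expect_equal(cm$mcc, mcc_onehot_oracle(as.character(truth),
                                         as.character(pred), c("a", "b", "c")),
               tolerance = 1e-12)
})

test_that("multiclass MCC equals one-hot correlation on random predictions", {
  set.seed(58)
  for (i in 1:10) {
    truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
    cm <- confusion_metrics(factor(truth, levels = c("a", "b", "c")),
                            factor(pred, levels = c("a", "b", "c")))
    expect_equal(cm$mcc, mcc_onehot_oracle(truth, pred, c("a", "b", "c")),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to sample order", {
  fc <- simulate_feature_cohort(n_per_class = 30L, s_signal = 3L,
                                n_noise = 4L, seed = 7L)
  panel <- c(fc$signal_proteins, fc$ig_cols)
  pm1 <- train_evaluate(fc, panel, n_mccv = 3L, seed = 4L, num_trees = 40L)
  perm <- sepsubtype:::with_seed(99L, sample(nrow(fc$table)))
  fc2 <- fc
  fc2$table <- fc$table[perm, ]
  pm2 <- train_evaluate(fc2, panel, n_mccv = 3L, seed = 4L, num_trees = 40L)
  # same metric distributions do not require identical splits; check the
  # deterministic parts: metric for a fixed confusion is order-free
  cm_a <- confusion_metrics(factor(fc$table$label), factor(fc$table$label))
  expect_equal(cm_a$accuracy, 1)
  expect_true(all(is.finite(pm1$metrics$test_mean)))
  expect_true(all(is.finite(pm2$metrics$test_mean)))
})

test_that("separable classes reach ceiling metrics; permuted labels do not", {
  fc <- simulate_feature_cohort(n_per_class = 50L, s_signal = 3L,
                                n_noise = 3L, effect = 12, seed = 8L)
  panel <- c(fc$signal_proteins, fc$ig_cols)
  pm <- train_evaluate(fc, panel, n_mccv = 8L, seed = 5L, num_trees = 80L)
  m <- pm$metrics
  expect_gt(m$test_mean[m$metric == "mcc"], 0.9)
  expect_gt(m$test_mean[m$metric == "auroc"], 0.98)
  fc_null <- fc
  fc_null$table$label <- sepsubtype:::with_seed(1L, sample(fc$table$label))
  pm0 <- train_evaluate(fc_null, panel, n_mccv = 8L, seed = 5L, num_trees = 80L)
  m0 <- pm0$metrics
  expect_lt(abs(m0$test_mean[m0$metric == "mcc"]), 0.15)
  expect_lt(abs(m0$test_mean[m0$metric == "auroc"] - 0.5), 0.12)
  # heavy train-test gap on permuted labels is flagged as overfitting
  expect_true(pm0$overfitting)
})
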