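ig_gene_pattern <- "^(IGH|IGK|IGL)|^JCHAIN$"
default_exclusions <- c("CRP", "FGG", "FGA", "FGB", "HBA2", "HBB", "HBD")

#' Greedy correlation pruning
#'
#' Scans columns in input order and drops a column if its absolute Pearson
#' correlation with any already-retained column strictly exceeds `threshold`
#' (pairwise-complete observations). Constant columns have undefined
#' correlations and are retained with a warning.
#'
#' @param x numeric matrix or data.frame of candidate columns.
#' @param threshold absolute-correlation limit (default 0.7; `r = 0.7`
#'   itself keeps both).
#' @return character vector of retained column names.
#' @export
correlation_prune <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), !is.null(colnames(x)))
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds)))
    warning("constant column(s) retained (undefined correlation): ",
            paste(colnames(x)[sds == 0 | is.na(sds)], collapse = ", "))
  kept <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (length(kept) && !is.na(sds[j]) && sds[j] > 0) {
      r <- suppressWarnings(
        stats::cor(x[, j], x[, kept, drop = FALSE],
                   use = "pairwise.complete.obs"))
      if (any(abs(r) > threshold, na.rm = TRUE)) next
    }
    kept <- c(kept, j)
  }
  colnames(x)[kept]
}

#' Assemble the supervised feature table
#'
#' Builds the classifier input from day-1 proteome, aggregated clinical
#' variables and orthogonal immunoglobulin concentrations: immunoglobulin
#' protein entries (gene prefix IGH/IGK/IGL, plus JCHAIN) are removed and
#' replaced by the IgG/IgA/IgM concentration columns; proteins covered by
#' routine assays (CRP, FGG, FGA, FGB, HBA2, HBB, HBD by default) are
#' excluded; the most-severe subtype (label 0) is dropped as too small for
#' robust modelling; columns with more than 30% missingness are removed;
#' clinical columns must separate the remaining subtypes (Kruskal-Wallis
#' p < 0.05); correlated features are pruned at |r| > 0.7 with the Ig
#' columns scanned first (they are mandated panel members), then proteins,
#' then clinical features.
#'
#' @param day1 an `intensity_matrix` of day-1 log2 intensities.
#' @param clinical_wide one-row-per-patient data.frame of aggregated
#'   clinical features (from [aggregate_daily()] with `fill_days = 2`);
#'   numeric columns only are used.
#' @param ig data.frame with patient_id, IgG, IgA, IgM (g/L).
#' @param labels named integer vector of severity-ordered subtype labels.
#' @param exclusions gene symbols to exclude besides immunoglobulin entries.
#' @param max_missing column missingness limit (default 0.30).
#' @param cor_threshold correlation-pruning limit (default 0.7).
#' @param kw_alpha Kruskal-Wallis significance level for clinical features.
#' @return a `feature_table`: list with `table` (patient_id, label, feature
#'   columns) and the column names per domain (`protein_cols`,
#'   `medical_cols`, `ig_cols`).
#' @export
build_feature_table <- function(day1, clinical_wide, ig, labels,
                                exclusions = default_exclusions,
                                max_missing = 0.30, cor_threshold = 0.7,
                                kw_alpha = 0.05) {
  stopifnot(inherits(day1, "intensity_matrix"))
  pts <- day1$samples$patient_id
  lab <- labels[pts]
  keep_pt <- !is.na(lab) & lab != 0L
  pts <- pts[keep_pt]
  lab <- lab[keep_pt]

  drop_gene <- grepl(ig_gene_pattern, day1$proteins$gene) |
    day1$proteins$gene %in% exclusions
  prot <- t(day1$values[!drop_gene, keep_pt, drop = FALSE])
  colnames(prot) <- day1$proteins$gene[!drop_gene]
  prot <- prot[, colMeans(is.na(prot)) <= max_missing, drop = FALSE]

  med <- clinical_wide[match(pts, clinical_wide$patient_id), , drop = FALSE]
  med_num <- med[, vapply(med, is.numeric, logical(1)), drop = FALSE]
  med_num <- med_num[, colMeans(is.na(med_num)) <= max_missing, drop = FALSE]
  kw_ok <- vapply(med_num, function(v)
    tryCatch(kruskal_wallis(v, lab)$p < kw_alpha, error = function(e) FALSE),
    logical(1))
  med_num <- med_num[, kw_ok, drop = FALSE]

  igm <- ig[match(pts, ig$patient_id), c("IgG", "IgA", "IgM"), drop = FALSE]
  if (any(colMeans(is.na(igm)) > max_missing))
    stop("immunoglobulin concentrations missing for more than ",
         100 * max_missing, "% of patients")

  all_feats <- cbind(as.matrix(igm), prot, as.matrix(med_num))
  rownames(all_feats) <- pts
  kept <- correlation_prune(all_feats, cor_threshold)

  ig_cols <- intersect(c("IgG", "IgA", "IgM"), kept)
  protein_cols <- intersect(colnames(prot), kept)
  medical_cols <- intersect(colnames(med_num), kept)
  tab <- data.frame(patient_id = pts, label = as.integer(lab),
                    all_feats[, c(ig_cols, protein_cols, medical_cols),
                              drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(table = tab, protein_cols = protein_cols,
                 medical_cols = medical_cols, ig_cols = ig_cols),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients, %d proteins + %d medical + %d Ig\n",
              nrow(x$table), length(x$protein_cols), length(x$medical_cols),
              length(x$ig_cols)))
  invisible(x)
}

# Stratified train/test split; guarantees >= 1 sample per class on each side.
stratified_split <- function(y, frac = 0.8) {
  train <- integer(0)
  for (l in unique(y)) {
    idx <- which(y == l)
    n_tr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

impute_median_cols <- function(X, medians = NULL) {
  if (is.null(medians))
    medians <- apply(X, 2, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- medians[j]
  }
  list(X = X, medians = medians)
}

fit_forest <- function(X, y, num_trees = 500L, seed = 1L) {
  w <- 1 / table(y)[y]  # class-balanced case weights
  ranger::ranger(x = as.data.frame(X), y = y, probability = TRUE,
                 num.trees = num_trees, min.node.size = 1,
                 case.weights = as.numeric(w),
                 seed = seed, num.threads = 1)
}

# Export a ranger probability forest as the flat tree arrays the C++ TreeSHAP
# kernel consumes; node covers are recomputed from the training matrix.
export_forest <- function(rf, X_train) {
  X_train <- as.matrix(X_train)
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    leaf <- ti$terminal
    vals <- as.matrix(ti[, grep("^pred\\.", names(ti)), drop = FALSE])
    vals[is.na(vals)] <- 0
    left <- ifelse(leaf, -1L, as.integer(ti$leftChild))
    right <- ifelse(leaf, -1L, as.integer(ti$rightChild))
    feature <- ifelse(leaf, -1L, as.integer(ti$splitvarID))
    threshold <- ifelse(leaf, 0, ti$splitval)
    cover <- cpp_tree_covers(left, right, feature, threshold, X_train)
    list(left = left, right = right, feature = feature,
         threshold = threshold, cover = cover, values = vals)
  })
}

#' Per-sample SHAP values for a fitted random forest
#'
#' Path-dependent TreeSHAP over the forest's trees, with node covers
#' recomputed from the training data. Attributions decompose each class
#' probability: for every sample and class they sum (with the baseline) to
#' the forest's predicted probability.
#'
#' @param rf a `ranger` probability forest.
#' @param X_train training feature matrix (defines the cover weights).
#' @param X matrix of samples to explain.
#' @return array `samples x features x classes` of SHAP values.
#' @export
forest_shap <- function(rf, X_train, X) {
  forest <- export_forest(rf, X_train)
  out <- cpp_forest_shap(forest, as.matrix(X))
  dimnames(out) <- list(rownames(X), colnames(X), NULL)
  out
}

#' SHAP-based feature ranking by Monte Carlo cross-validation
#'
#' For each MCCV iteration: stratified 80/20 split, median imputation within
#' the iteration (training medians, applied to both parts), a random forest
#' fit on all features, and mean absolute SHAP attribution per feature on
#' the held-out part. Features are ranked within each domain (medical,
#' protein) per iteration; the output reports the median rank per feature
#' across iterations. Immunoglobulin columns are included in every model but
#' not ranked (they are fixed members of the final panel). Deterministic
#' given `seed`.
#'
#' @param ft a `feature_table`.
#' @param n_mccv number of MCCV iterations (default 100).
#' @param split training fraction (default 0.8).
#' @param seed master seed.
#' @param num_trees trees per forest (default 500).
#' @return a `selection_ranks` object: `median_rank` per domain,
#'   `rank_iter` per domain (features x iterations matrices), feature order
#'   per domain (best median rank first).
#' @export
shap_rank <- function(ft, n_mccv = 100L, split = 0.8, seed = 1L,
                      num_trees = 500L) {
  stopifnot(inherits(ft, "feature_table"))
  tab <- ft$table
  y <- factor(tab$label)
  if (any(table(y) < 20))
    warning("fewer than 20 patients in a class; rankings may be unstable")
  feat_cols <- c(ft$ig_cols, ft$protein_cols, ft$medical_cols)
  X <- as.matrix(tab[, feat_cols, drop = FALSE])
  seeds <- derive_seeds(seed, n_mccv, salt = 31L)
  rank_prot <- matrix(NA_real_, length(ft$protein_cols), n_mccv,
                      dimnames = list(ft$protein_cols, NULL))
  rank_med <- matrix(NA_real_, length(ft$medical_cols), n_mccv,
                     dimnames = list(ft$medical_cols, NULL))
  for (i in seq_len(n_mccv)) {
    with_seed(seeds[i], {
      tr <- stratified_split(y, split)
      imp <- impute_median_cols(X[tr, , drop = FALSE])
      Xtr <- imp$X
      Xte <- impute_median_cols(X[-tr, , drop = FALSE], imp$medians)$X
      rf <- fit_forest(Xtr, y[tr], num_trees, seed = seeds[i])
      sh <- forest_shap(rf, Xtr, Xte)
      imp_score <- apply(abs(sh), 2, mean)  # mean |phi| over samples, classes
      if (length(ft$protein_cols))
        rank_prot[, i] <- rank(-imp_score[ft$protein_cols],
                               ties.method = "average")
      if (length(ft$medical_cols))
        rank_med[, i] <- rank(-imp_score[ft$medical_cols],
                              ties.method = "average")
    })
  }
  med_p <- apply(rank_prot, 1, stats::median)
  med_m <- if (nrow(rank_med)) apply(rank_med, 1, stats::median) else numeric(0)
  order_domain <- function(med, m) {
    if (!length(med)) return(character(0))
    names(med)[order(med, rowMeans(m), names(med))]
  }
  structure(list(median_rank = list(protein = med_p, medical = med_m),
                 rank_iter = list(protein = rank_prot, medical = rank_med),
                 order = list(protein = order_domain(med_p, rank_prot),
                              medical = order_domain(med_m, rank_med)),
                 n_mccv = n_mccv, seed = seed),
            class = "selection_ranks")
}

# Weighted (support-proportional) recall of a forest over MCCV iterations
# for a fixed feature set.
mccv_recall <- function(tab, y, cols, n_mccv, split, seeds, num_trees) {
  X <- as.matrix(tab[, cols, drop = FALSE])
  rec <- numeric(n_mccv)
  for (i in seq_len(n_mccv)) {
    rec[i] <- with_seed(seeds[i], {
      tr <- stratified_split(y, split)
      imp <- impute_median_cols(X[tr, , drop = FALSE])
      Xte <- impute_median_cols(X[-tr, , drop = FALSE], imp$medians)$X
      rf <- fit_forest(imp$X, y[tr], num_trees, seed = seeds[i])
      pred <- predict(rf, data = as.data.frame(Xte), num.threads = 1)$predictions
      cls <- factor(colnames(pred)[max.col(pred, ties.method = "first")],
                    levels = levels(y))
      confusion_metrics(y[-tr], cls)$recall_weighted
    })
  }
  c(mean = mean(rec), sd = stats::sd(rec))
}

#' Nested MCCV feature-count scan
#'
#' Outer loop over the number of medical features, inner loop over the
#' number of proteins, both added in median-SHAP-rank order; each grid cell
#' is scored by the mean (and SD) of the weighted test recall over `n_mccv`
#' stratified 80/20 MCCV splits of a random forest on the selected features
#' (plus the immunoglobulin columns, which are always included). The
#' `n_medical = 0` row is the proteins-only curve used for knee-point panel
#' sizing.
#'
#' @param ft a `feature_table`.
#' @param ranks a `selection_ranks` from [shap_rank()].
#' @param grid_medical integer vector of medical feature counts (may
#'   include 0).
#' @param grid_protein integer vector of protein counts.
#' @param n_mccv MCCV iterations per cell (default 100).
#' @param split training fraction.
#' @param seed master seed.
#' @param num_trees trees per forest.
#' @return a `selection_trace`: `surface` data.frame (n_medical, n_protein,
#'   recall_mean, recall_sd), the rank tables, and the feature orders used.
#' @export
nested_selection <- function(ft, ranks, grid_medical = 0:5,
                             grid_protein = 1:20, n_mccv = 100L,
                             split = 0.8, seed = 1L, num_trees = 500L) {
  stopifnot(inherits(ft, "feature_table"), inherits(ranks, "selection_ranks"))
  if (max(grid_protein) > length(ranks$order$protein)) {
    warning("protein grid truncated to available features")
    grid_protein <- grid_protein[grid_protein <= length(ranks$order$protein)]
  }
  if (max(grid_medical) > length(ranks$order$medical)) {
    warning("medical grid truncated to available features")
    grid_medical <- grid_medical[grid_medical <= length(ranks$order$medical)]
  }
  y <- factor(ft$table$label)
  seeds <- derive_seeds(seed, n_mccv, salt = 57L)
  grid <- expand.grid(n_medical = sort(unique(grid_medical)),
                      n_protein = sort(unique(grid_protein)))
  res <- t(apply(grid, 1, function(g) {
    cols <- c(ft$ig_cols,
              ranks$order$protein[seq_len(g[["n_protein"]])],
              if (g[["n_medical"]] > 0)
                ranks$order$medical[seq_len(g[["n_medical"]])])
    mccv_recall(ft$table, y, cols, n_mccv, split, seeds, num_trees)
  }))
  surface <- cbind(grid, recall_mean = res[, "mean"], recall_sd = res[, "sd"])
  structure(list(surface = surface, ranks = ranks,
                 n_mccv = n_mccv, seed = seed),
            class = "selection_trace")
}

#' Knee-point detection on a concave increasing curve
#'
#' The Kneedle rule: min-max normalize both axes, form the difference curve
#' `d(x) = y_norm - x_norm`, and return the x at its maximum (sensitivity
#' S = 1, no smoothing). A flat, linear or monotone-decreasing curve has no
#' knee and yields `NA`.
#'
#' @param x feature counts (increasing).
#' @param y mean recall at each count.
#' @return the x value at the knee, or `NA_real_` if no knee exists.
#' @export
knee_point <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (diff(range(y)) == 0 || all(diff(y) <= 0)) return(NA_real_)
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- yn - xn
  if (max(d) <= 0) return(NA_real_)
  x[which.max(d)]
}

#' Finalize the minimal protein panel
#'
#' Given the knee-point protein count `n_star`, selects the proteins most
#' frequently appearing in the per-iteration SHAP top-`n_star` sets across
#' the ranking MCCV iterations (ties broken by better median rank, then
#' name) and appends the immunoglobulin columns. The final panel contains no
#' clinical features.
#'
#' @param trace a `selection_trace` (or `selection_ranks`).
#' @param n_star panel protein count (the knee).
#' @param ig_features immunoglobulin columns appended to every panel.
#' @return list with `proteins`, `panel` (proteins + Ig columns) and the
#'   selection-frequency table.
#' @export
finalize_panel <- function(trace, n_star,
                           ig_features = c("IgG", "IgA", "IgM")) {
  ranks <- if (inherits(trace, "selection_trace")) trace$ranks else trace
  stopifnot(inherits(ranks, "selection_ranks"), is.finite(n_star), n_star >= 1)
  ri <- ranks$rank_iter$protein
  freq <- rowMeans(ri <= n_star)
  med <- ranks$median_rank$protein
  ord <- order(-freq, med, names(freq))
  proteins <- names(freq)[ord][seq_len(min(n_star, length(freq)))]
  list(proteins = proteins,
       panel = c(proteins, ig_features),
       selection_freq = data.frame(feature = names(freq)[ord],
                                   freq = freq[ord],
                                   median_rank = med[ord],
                                   row.names = NULL))
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, weighted (support-proportional) precision, recall and F1, and
#' the multiclass Matthews correlation coefficient in Gorodkin's
#' covariance form (equal to the Pearson correlation between one-hot truth
#' and prediction matrices).
#'
#' @param truth,pred factors over the same levels.
#' @return list of scalar metrics.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  C <- table(truth, pred)
  N <- sum(C)
  support <- rowSums(C)
  pred_tot <- colSums(C)
  prec_k <- ifelse(pred_tot > 0, diag(C) / pred_tot, 0)
  rec_k <- ifelse(support > 0, diag(C) / support, 0)
  f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  w <- support / N
  trc <- sum(diag(C))
  denom <- sqrt(N^2 - sum(pred_tot^2)) * sqrt(N^2 - sum(support^2))
  mcc <- if (denom == 0) 0 else (N * trc - sum(pred_tot * support)) / denom
  list(accuracy = trc / N,
       precision_weighted = sum(w * prec_k),
       recall_weighted = sum(w * rec_k),
       f1_weighted = sum(w * f1_k),
       mcc = mcc,
       per_class_recall = rec_k)
}

#' Macro one-vs-rest AUROC
#'
#' Mean over classes of the binary AUROC of the class-probability column
#' against the one-vs-rest label.
#'
#' @param truth factor of true labels.
#' @param prob matrix of class probabilities (columns named by level).
#' @return scalar macro AUROC.
#' @export
auroc_macro <- function(truth, prob) {
  truth <- factor(truth)
  aucs <- vapply(levels(truth), function(l) {
    resp <- truth == l
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp, predictor = prob[, l],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Final-panel training and MCCV evaluation
#'
#' Stratified 80/20 MCCV of a random forest on the panel features. Per
#' iteration, accuracy, macro one-vs-rest AUROC, weighted F1, multiclass
#' MCC, weighted precision and weighted recall are computed on the training
#' and on the test part; the table reports mean and SD per metric and side.
#' A train-minus-test mean gap above 0.1 in any metric is flagged as
#' overfitting.
#'
#' @param ft a `feature_table`.
#' @param panel character vector of feature columns (e.g.
#'   `finalize_panel()$panel`).
#' @param n_mccv MCCV iterations (default 100).
#' @param split training fraction.
#' @param seed master seed.
#' @param num_trees trees per forest.
#' @return a `panel_model`: metric table (`metrics`), overfitting flag, the
#'   panel, and a final forest trained on all data.
#' @export
train_evaluate <- function(ft, panel, n_mccv = 100L, split = 0.8, seed = 1L,
                           num_trees = 500L) {
  stopifnot(inherits(ft, "feature_table"),
            all(panel %in% names(ft$table)))
  y <- factor(ft$table$label)
  X <- as.matrix(ft$table[, panel, drop = FALSE])
  seeds <- derive_seeds(seed, n_mccv + 1L, salt = 83L)
  metric_names <- c("accuracy", "auroc", "f1", "mcc", "precision", "recall")
  res <- array(NA_real_, c(n_mccv, length(metric_names), 2),
               dimnames = list(NULL, metric_names, c("test", "train")))
  eval_side <- function(rf, Xs, ys) {
    prob <- predict(rf, data = as.data.frame(Xs),
                    num.threads = 1)$predictions
    cls <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                  levels = levels(ys))
    cm <- confusion_metrics(ys, cls)
    c(accuracy = cm$accuracy, auroc = auroc_macro(ys, prob),
      f1 = cm$f1_weighted, mcc = cm$mcc,
      precision = cm$precision_weighted, recall = cm$recall_weighted)
  }
  for (i in seq_len(n_mccv)) {
    with_seed(seeds[i], {
      tr <- stratified_split(y, split)
      imp <- impute_median_cols(X[tr, , drop = FALSE])
      Xte <- impute_median_cols(X[-tr, , drop = FALSE], imp$medians)$X
      rf <- fit_forest(imp$X, y[tr], num_trees, seed = seeds[i])
      res[i, , "test"] <- eval_side(rf, Xte, y[-tr])
      res[i, , "train"] <- eval_side(rf, imp$X, y[tr])
    })
  }
  metrics <- data.frame(metric = metric_names,
                        test_mean = apply(res[, , "test"], 2, mean),
                        test_sd = apply(res[, , "test"], 2, stats::sd),
                        train_mean = apply(res[, , "train"], 2, mean),
                        train_sd = apply(res[, , "train"], 2, stats::sd),
                        row.names = NULL)
  metrics$gap <- metrics$train_mean - metrics$test_mean
  final <- with_seed(seeds[n_mccv + 1L], {
    imp <- impute_median_cols(X)
    fit_forest(imp$X, y, num_trees, seed = seeds[n_mccv + 1L])
  })
  structure(list(schema = "sepsubtype-panel-v1",
                 panel = panel, metrics = metrics,
                 overfitting = any(metrics$gap > 0.1),
                 forest = final, n_mccv = n_mccv, seed = seed),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d features, %dx MCCV%s\n", length(x$panel),
              x$n_mccv, if (x$overfitting) " (overfitting flagged)" else ""))
  print(x$metrics, digits = 3)
  invisible(x)
}
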