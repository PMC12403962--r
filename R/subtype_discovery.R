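#' Fit a PCA basis on day-1 z-scores
#'
#' Principal component analysis of the day-1 z-matrix, truncated to the
#' smallest number of components whose cumulative explained-variance fraction
#' strictly exceeds `variance_target`. Eigenvector sign ambiguity is removed
#' by making each loading vector's largest-magnitude entry positive, so
#' serialized bases are comparable across runs.
#'
#' @param z numeric matrix, samples x proteins (from [apply_standardizer()]).
#' @param variance_target cumulative explained-variance fraction to exceed
#'   (default 0.70).
#' @return a `pca_basis` with loadings (proteins x m), the per-protein basis
#'   mean used for centering, explained-variance fractions and `m`.
#' @export
fit_pca <- function(z, variance_target = 0.70) {
  stopifnot(is.matrix(z), !anyNA(z))
  if (variance_target >= 1 || variance_target <= 0)
    stop("variance_target must be in (0, 1)")
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  m <- which(cumsum(frac) > variance_target)[1]
  if (is.na(m)) m <- length(frac)
  load <- pc$rotation[, seq_len(m), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  structure(list(loadings = load,
                 center = pc$center,
                 var_frac = frac[seq_len(m)],
                 cum_var = cumsum(frac)[m],
                 m = m),
            class = "pca_basis")
}

#' Project samples into a fitted PC space
#'
#' Scores are the basis-mean-centred data times the loadings. Day-4 data are
#' always projected with the day-1 basis, never refit.
#'
#' @param z samples x proteins matrix in the basis' protein order.
#' @param basis a `pca_basis` from [fit_pca()].
#' @return samples x m score matrix.
#' @export
project_pca <- function(z, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  if (ncol(z) != nrow(basis$loadings))
    stop("dimension mismatch: matrix has ", ncol(z), " proteins, basis ",
         nrow(basis$loadings))
  sweep(z, 2, basis$center) %*% basis$loadings
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' k-means clustering with k-means++ initialisation
#'
#' Runs Lloyd's algorithm `n_init` times from k-means++ seedings and keeps
#' the run with the lowest total within-cluster sum of squares. Runs that
#' converge to an empty cluster are re-initialised. Deterministic given
#' `seed`.
#'
#' @param x samples x features score matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_init number of restarts (default 25).
#' @param iter_max Lloyd iteration cap (default 300).
#' @return list with `centroids` (k x features), `labels` (0-based integers)
#'   and `tot_withinss`.
#' @export
fit_kmeans <- function(x, k, seed = 1L, n_init = 25L, iter_max = 300L) {
  stopifnot(is.matrix(x), k >= 2, n_init >= 1)
  if (k > nrow(unique(as.data.frame(x))))
    stop("k exceeds the number of distinct points")
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- NULL
      for (attempt in 1:20) {
        centers <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) stop("k-means failed to produce ", k,
                             " non-empty clusters")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(centroids = unname(best$centers),
         labels = as.integer(best$cluster) - 1L,
         tot_withinss = best$tot.withinss)
  })
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio `(S_i + S_j) / M_ij`, where `S_i` is
#' the mean Euclidean distance of cluster members to their centroid and
#' `M_ij` the distance between centroids. Lower is better.
#'
#' @param x samples x features matrix.
#' @param labels integer cluster labels.
#' @return the index (a scalar).
#' @export
davies_bouldin <- function(x, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  stopifnot(k >= 2)
  cent <- do.call(rbind, lapply(labs, function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  S <- vapply(seq_len(k), function(i) {
    xi <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  R <- outer(S, S, `+`) / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Cluster-count diagnostics: silhouette, gap statistic, Davies-Bouldin
#'
#' For each `k` in `k_range` the mean silhouette width and Davies-Bouldin
#' index of the k-means partition are computed; the gap statistic (uniform
#' reference over the bounding box of the scores, `B_reference` draws,
#' squared-distance pooled within-cluster dispersion) is additionally
#' evaluated at `k = 1`. The gap rule suggests the smallest `k` with
#' `Gap(k) >= Gap(k+1) - s_{k+1}`.
#'
#' @param x samples x features score matrix.
#' @param k_range candidate cluster counts (subset of 2..10).
#' @param B_reference number of gap-statistic reference draws (default 50).
#' @param seed integer seed.
#' @param n_init k-means restarts per evaluation.
#' @return data.frame with one row per `k` (silhouette, Davies-Bouldin, gap,
#'   gap SE; the `k = 1` row carries only gap columns) plus a `suggested`
#'   attribute listing the k preferred by each diagnostic.
#' @export
choose_k <- function(x, k_range = 2:8, B_reference = 50L, seed = 1L,
                     n_init = 10L) {
  stopifnot(is.matrix(x), all(k_range >= 2), all(k_range <= 10))
  if (max(k_range) >= nrow(x)) stop("k must be below the number of samples")
  k_range <- sort(unique(as.integer(k_range)))
  seeds <- derive_seeds(seed, length(k_range) + 1L, salt = 7L)

  d <- stats::dist(x)
  sil <- db <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    km <- fit_kmeans(x, k_range[i], seed = seeds[i], n_init = n_init)
    sil[i] <- mean(cluster::silhouette(km$labels + 1L, d)[, "sil_width"])
    db[i] <- davies_bouldin(x, km$labels)
  }

  kmax <- max(k_range)
  clus_fun <- function(x, k) {
    if (k == 1) list(cluster = rep(1L, nrow(x)))
    else list(cluster = fit_kmeans(x, k, seed = seeds[length(seeds)],
                                   n_init = n_init)$labels + 1L)
  }
  gap_fit <- with_seed(seeds[length(seeds)],
                       cluster::clusGap(x, FUNcluster = clus_fun, K.max = kmax,
                                        B = B_reference, d.power = 2,
                                        spaceH0 = "original", verbose = FALSE))
  gtab <- gap_fit$Tab
  gap_k <- cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                          method = "Tibs2001SEmax")

  out <- data.frame(k = c(1L, k_range),
                    silhouette = c(NA, sil),
                    davies_bouldin = c(NA, db),
                    gap = gtab[c(1L, k_range), "gap"],
                    gap_se = gtab[c(1L, k_range), "SE.sim"])
  attr(out, "suggested") <- list(silhouette = k_range[which.max(sil)],
                                 davies_bouldin = k_range[which.min(db)],
                                 gap = as.integer(gap_k))
  out
}

#' Severity-ordered relabelling of raw clusters
#'
#' Renames raw cluster indices `0..k-1` in order of strictly decreasing
#' median day-1 SOFA score, so label 0 is always the most severe subtype.
#' Ties are broken by smaller cluster size first, then by original index.
#'
#' @param labels integer raw cluster labels (0-based), one per patient.
#' @param sofa numeric day-1 SOFA score per patient (same order).
#' @return integer `label_map` of length `k`: `label_map[old + 1]` is the new
#'   severity-ordered label of raw cluster `old`.
#' @export
relabel_by_severity <- function(labels, sofa) {
  stopifnot(length(labels) == length(sofa))
  labs <- sort(unique(labels))
  med <- vapply(labs, function(l) stats::median(sofa[labels == l], na.rm = TRUE),
                numeric(1))
  if (any(!is.finite(med))) stop("every cluster needs at least one SOFA value")
  size <- vapply(labs, function(l) sum(labels == l), numeric(1))
  ord <- order(-med, size, labs)
  label_map <- integer(length(labs))
  label_map[ord] <- seq_along(labs) - 1L
  label_map
}

#' Assign samples to the nearest subtype centroid
#'
#' Each score vector is assigned to the cluster whose centroid is nearest in
#' Euclidean distance; labels are reported on the severity-ordered scale via
#' the model's `label_map`. Exact distance ties go to the lowest
#' severity-ordered label.
#'
#' @param scores samples x m matrix in the model's PC space.
#' @param model a `subtype_model` (or any list with `centroids` and
#'   `label_map`).
#' @return integer vector of severity-ordered labels.
#' @export
assign_subtypes <- function(scores, model) {
  cent <- model$centroids
  stopifnot(ncol(scores) == ncol(cent))
  map <- model$label_map %||% (seq_len(nrow(cent)) - 1L)
  d2 <- outer(rowSums(scores^2), rep(1, nrow(cent))) -
    2 * scores %*% t(cent) +
    outer(rep(1, nrow(scores)), rowSums(cent^2))
  vapply(seq_len(nrow(scores)), function(i) {
    ties <- which(d2[i, ] == min(d2[i, ]))
    min(map[ties])
  }, integer(1))
}

#' Tabulate day-1 to day-4 subtype trajectories
#'
#' Counts patients by (day-1 label, day-4 label, 30-day outcome) over the
#' intersection of patients with both-day samples.
#'
#' @param labels_day1 named integer vector (names = patient ids).
#' @param labels_day4 named integer vector for followed patients.
#' @param dead30 named logical vector of 30-day death per patient.
#' @return data.frame (day1, day4, outcome, n) covering all combinations,
#'   plus attribute `n_patients`.
#' @export
trajectories <- function(labels_day1, labels_day4, dead30) {
  pts <- names(labels_day4)
  orphan <- setdiff(pts, names(labels_day1))
  if (length(orphan))
    stop("patients with day-4 but no day-1 label: ",
         paste(orphan, collapse = ", "))
  l1 <- labels_day1[pts]
  outc <- factor(ifelse(dead30[pts], "deceased", "survived"),
                 levels = c("survived", "deceased"))
  labs <- sort(unique(c(l1, labels_day4)))
  tab <- as.data.frame(table(day1 = factor(l1, levels = labs),
                             day4 = factor(labels_day4, levels = labs),
                             outcome = outc))
  names(tab)[4] <- "n"
  tab$day1 <- as.integer(as.character(tab$day1))
  tab$day4 <- as.integer(as.character(tab$day4))
  attr(tab, "n_patients") <- length(pts)
  tab
}

#' Fit the full subtype model on day-1 data
#'
#' Chains the day-1 pipeline: completeness filter against day 4, per-matrix
#' median imputation, z-standardization, PCA truncation, k-means and
#' severity-ordered relabelling. The returned model freezes every parameter
#' needed to assign day-4 or new samples (standardizer, basis, centroids,
#' label map) and is never refit downstream.
#'
#' @param day1,day4 `intensity_matrix` objects.
#' @param sofa named numeric vector of day-1 SOFA scores per patient id.
#' @param k number of subtypes (default 4; diagnostics are advisory, the
#'   cluster count is always taken from configuration).
#' @param max_missing completeness threshold (default 0.30).
#' @param variance_target PCA cumulative-variance target (default 0.70).
#' @param seed integer seed.
#' @param n_init k-means restarts (default 25).
#' @return a `subtype_model`, with day-1 severity-ordered labels in
#'   `$labels_day1` (named by patient id).
#' @export
fit_subtype_model <- function(day1, day4, sofa, k = 4L, max_missing = 0.30,
                              variance_target = 0.70, seed = 1L,
                              n_init = 25L) {
  keep <- filter_completeness(day1, day4, max_missing)
  d1 <- impute_median(subset_proteins(day1, keep))
  params <- fit_standardizer(d1)
  z1 <- apply_standardizer(d1, params)
  basis <- fit_pca(z1, variance_target)
  scores <- project_pca(z1, basis)
  km <- fit_kmeans(scores, k, seed = seed, n_init = n_init)
  sofa_aligned <- sofa[d1$samples$patient_id]
  label_map <- relabel_by_severity(km$labels, sofa_aligned)
  labels <- label_map[km$labels + 1L]
  names(labels) <- d1$samples$patient_id
  structure(list(schema = "sepsubtype-model-v1",
                 protein_ids = keep,
                 params = params,
                 basis = basis,
                 k = as.integer(k),
                 centroids = km$centroids,
                 label_map = label_map,
                 seed = as.integer(seed),
                 n_init = as.integer(n_init),
                 variance_target = variance_target,
                 max_missing = max_missing,
                 labels_day1 = labels),
            class = "subtype_model")
}

#' Assign a new matrix (e.g. day 4) with a frozen subtype model
#'
#' Restricts the matrix to the model's proteins, imputes medians within the
#' matrix, applies the frozen day-1 standardizer, projects with the frozen
#' basis and assigns by nearest centroid.
#'
#' @param x an `intensity_matrix`.
#' @param model a `subtype_model`.
#' @return named integer vector of severity-ordered labels (names = patient
#'   ids).
#' @export
assign_matrix <- function(x, model) {
  stopifnot(inherits(model, "subtype_model"))
  xm <- impute_median(subset_proteins(x, model$protein_ids))
  z <- apply_standardizer(xm, model$params)
  labels <- assign_subtypes(project_pca(z, model$basis), model)
  names(labels) <- xm$samples$patient_id
  labels
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %d proteins, %d PCs (%.1f%% var), k = %d\n",
              length(x$protein_ids), x$basis$m, 100 * x$basis$cum_var, x$k))
  invisible(x)
}

#' Serialize a subtype model to JSON
#'
#' Writes the frozen model (standardizer, PCA basis, centroids, label map)
#' as a single library-free JSON document, schema `sepsubtype-model-v1`.
#'
#' @param model a `subtype_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subtype_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  doc <- list(schema = model$schema,
              protein_ids = model$protein_ids,
              standardizer = list(mean = unname(model$params$mean),
                                  sd = unname(model$params$sd)),
              pca = list(loadings = unname(model$basis$loadings),
                         center = unname(model$basis$center),
                         var_frac = model$basis$var_frac,
                         m = model$basis$m),
              k = model$k,
              centroids = model$centroids,
              label_map = model$label_map,
              seed = model$seed,
              n_init = model$n_init,
              variance_target = model$variance_target,
              max_missing = model$max_missing)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a subtype model from JSON
#'
#' @param path a file written by [write_subtype_model()].
#' @return a `subtype_model` (without training labels).
#' @export
read_subtype_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "sepsubtype-model-v1"))
    stop("unrecognized model schema: ", doc$schema)
  params <- structure(list(mean = stats::setNames(doc$standardizer$mean,
                                                  doc$protein_ids),
                           sd = stats::setNames(doc$standardizer$sd,
                                                doc$protein_ids),
                           protein_ids = doc$protein_ids),
                      class = "standardization_params")
  basis <- structure(list(loadings = as.matrix(doc$pca$loadings),
                          center = stats::setNames(doc$pca$center,
                                                   doc$protein_ids),
                          var_frac = doc$pca$var_frac,
                          cum_var = sum(doc$pca$var_frac),
                          m = doc$pca$m),
                     class = "pca_basis")
  structure(list(schema = doc$schema,
                 protein_ids = doc$protein_ids,
                 params = params,
                 basis = basis,
                 k = as.integer(doc$k),
                 centroids = as.matrix(doc$centroids),
                 label_map = as.integer(doc$label_map),
                 seed = as.integer(doc$seed),
                 n_init = as.integer(doc$n_init),
                 variance_target = doc$variance_target,
                 max_missing = doc$max_missing),
            class = "subtype_model")
}
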