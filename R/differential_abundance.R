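#' Per-protein one-way ANOVA across subtypes
#'
#' Fixed-effects one-way ANOVA on log2 intensities, one test per protein.
#' Proteins with fewer than two observed values in any group, or with zero
#' within-group variance, are flagged untestable and excluded from the FDR
#' denominator.
#'
#' @param x an `intensity_matrix` (missing cells are dropped per protein).
#' @param labels integer subtype label per sample (column).
#' @return data.frame: protein_id, F, p, testable.
#' @export
anova_per_protein <- function(x, labels) {
  stopifnot(inherits(x, "intensity_matrix"),
            length(labels) == ncol(x$values))
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least two groups")
  res <- t(apply(x$values, 1, function(v) {
    ok <- !is.na(v)
    tab <- table(g[ok])
    if (length(tab) < nlevels(g) || any(tab < 2)) return(c(NA, NA))
    if (all(tapply(v[ok], g[ok], stats::var) == 0)) return(c(NA, NA))
    ft <- stats::oneway.test(v[ok] ~ g[ok], var.equal = TRUE)
    c(unname(ft$statistic), ft$p.value)
  }))
  data.frame(protein_id = x$proteins$protein_id,
             F = res[, 1], p = res[, 2],
             testable = is.finite(res[, 1]),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed; NAs are
#'   excluded from the denominator and returned as NA).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Tukey's post-hoc test per protein
#'
#' Studentized-range pairwise comparisons for every unordered pair of
#' subtypes, with pooled within-group variance; unequal group sizes are
#' handled by the Tukey-Kramer form. Pairs are reported as
#' `"<lower>-<higher>"` on the severity-ordered label scale.
#'
#' @inheritParams anova_per_protein
#' @return data.frame: protein_id, then one p-value column `p_<i>_<j>` per
#'   pair. Untestable proteins get NA rows.
#' @export
tukey_posthoc <- function(x, labels) {
  stopifnot(inherits(x, "intensity_matrix"),
            length(labels) == ncol(x$values))
  g <- factor(labels)
  labs <- levels(g)
  pairs <- utils::combn(labs, 2)
  pair_names <- paste0("p_", pairs[1, ], "_", pairs[2, ])
  key <- paste0(pairs[2, ], "-", pairs[1, ])  # TukeyHSD orientation
  res <- t(apply(x$values, 1, function(v) {
    ok <- !is.na(v)
    tab <- table(g[ok])
    if (length(tab) < nlevels(g) || any(tab < 2)) return(rep(NA_real_, ncol(pairs)))
    if (all(tapply(v[ok], g[ok], stats::var) == 0)) return(rep(NA_real_, ncol(pairs)))
    fit <- stats::aov(v[ok] ~ g[ok])
    tk <- stats::TukeyHSD(fit)[[1]]
    tk[key, "p adj"]
  }))
  if (ncol(pairs) == 1) res <- matrix(as.vector(res), ncol = 1)
  out <- data.frame(protein_id = x$proteins$protein_id, res,
                    stringsAsFactors = FALSE)
  names(out) <- c("protein_id", pair_names)
  out
}

#' Ratio of linear-scale means between two subtypes
#'
#' Intensities live on the log2 scale; the ratio of means is computed on the
#' linear scale (`2^x`), lower-numbered cluster in the numerator, so it reads
#' as a fold change of the first-named subtype over the second.
#'
#' @inheritParams anova_per_protein
#' @return data.frame: protein_id, then one column `rom_<i>_<j>` per pair.
#' @export
ratio_of_means <- function(x, labels) {
  stopifnot(inherits(x, "intensity_matrix"),
            length(labels) == ncol(x$values))
  g <- factor(labels)
  labs <- levels(g)
  lin <- 2^x$values
  grp_means <- matrix(vapply(labs, function(l)
    rowMeans(lin[, g == l, drop = FALSE], na.rm = TRUE),
    numeric(nrow(lin))), nrow = nrow(lin), dimnames = list(NULL, labs))
  pairs <- utils::combn(labs, 2)
  rom <- matrix(vapply(seq_len(ncol(pairs)), function(j)
    grp_means[, pairs[1, j]] / grp_means[, pairs[2, j]],
    numeric(nrow(lin))), nrow = nrow(lin))
  out <- data.frame(protein_id = x$proteins$protein_id, rom,
                    stringsAsFactors = FALSE)
  names(out) <- c("protein_id", paste0("rom_", pairs[1, ], "_", pairs[2, ]))
  out
}

#' Three-condition significance gate
#'
#' A pair is significant iff the ANOVA FDR-adjusted p-value is `<= p_fdr_max`,
#' the pair's Tukey p-value is `<= p_pair_max`, and the pair's ratio of means
#' lies outside `(rom_down, rom_up)`. A protein is globally significant iff
#' any pair is. The same pair must pass all three conditions (conjunctive
#' per-pair reading).
#'
#' @param p_fdr vector of FDR-adjusted ANOVA p-values per protein.
#' @param tukey data.frame from [tukey_posthoc()].
#' @param rom data.frame from [ratio_of_means()].
#' @param p_fdr_max,p_pair_max,rom_up,rom_down gate thresholds (defaults
#'   0.05, 0.05, 1.5, 0.67).
#' @return data.frame: protein_id, one logical `sig_<i>_<j>` per pair,
#'   and `significant`.
#' @export
significance_gate <- function(p_fdr, tukey, rom,
                              p_fdr_max = 0.05, p_pair_max = 0.05,
                              rom_up = 1.5, rom_down = 0.67) {
  stopifnot(length(p_fdr) == nrow(tukey), nrow(tukey) == nrow(rom))
  pair_tags <- sub("^p_", "", names(tukey)[-1])
  flags <- vapply(pair_tags, function(tag) {
    tp <- tukey[[paste0("p_", tag)]]
    rv <- rom[[paste0("rom_", tag)]]
    !is.na(p_fdr) & !is.na(tp) &
      p_fdr <= p_fdr_max & tp <= p_pair_max &
      (rv >= rom_up | rv <= rom_down)
  }, logical(nrow(tukey)))
  flags <- matrix(flags, nrow = nrow(tukey),
                  dimnames = list(NULL, paste0("sig_", pair_tags)))
  out <- data.frame(protein_id = tukey$protein_id, flags,
                    significant = rowSums(flags) > 0,
                    stringsAsFactors = FALSE)
  out
}

#' Abundance-pattern clustering of significant proteins
#'
#' Hierarchical agglomeration of per-protein profiles with dissimilarity
#' `1 - Pearson correlation` and Ward's linkage (Lance-Williams Ward update
#' applied directly to the correlation dissimilarities, as in the source
#' figure; note Ward's method formally assumes squared Euclidean distances).
#' The tree is cut into `n_branches` branches, labelled in order of
#' decreasing branch size.
#'
#' @param profiles numeric matrix, proteins x clusters (e.g. z-scored
#'   cluster-mean profiles; correlation is location/scale invariant).
#' @param n_branches number of branches to cut (default 5 at day 1, 4 at
#'   day 4).
#' @return integer pattern label per protein (1 = largest branch), named by
#'   rownames.
#' @export
abundance_patterns <- function(profiles, n_branches = 5L) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= n_branches)
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0))
    stop("constant profile (undefined correlation) for protein(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = "ward.D")
  raw <- stats::cutree(hc, k = n_branches)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(n_branches)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(n_branches)
  out <- relabel[raw]
  names(out) <- rownames(profiles)
  out
}

#' Per-protein z-scored cluster-mean profiles
#'
#' For each protein, the mean log2 intensity per cluster, z-scored across
#' clusters; the input to [abundance_patterns()].
#'
#' @inheritParams anova_per_protein
#' @return proteins x clusters matrix.
#' @export
cluster_mean_profiles <- function(x, labels) {
  g <- factor(labels)
  m <- vapply(levels(g), function(l)
    rowMeans(x$values[, g == l, drop = FALSE], na.rm = TRUE),
    numeric(nrow(x$values)))
  rownames(m) <- x$proteins$protein_id
  t(scale(t(m)))[, , drop = FALSE]
}

#' Full differential-abundance analysis for one timepoint
#'
#' Runs ANOVA, Benjamini-Hochberg correction (FDR denominator = testable
#' proteins at this timepoint; day 1 and day 4 are corrected separately),
#' Tukey's post-hoc test, linear-scale ratios of means, the three-condition
#' significance gate and abundance-pattern clustering of the significant
#' proteins.
#'
#' @inheritParams anova_per_protein
#' @param n_branches pattern branches for the significant-protein dendrogram.
#' @param ... gate thresholds passed to [significance_gate()].
#' @return data.frame with one row per protein: F, p, p_fdr, per-pair Tukey
#'   p, per-pair RoM, per-pair significance flags, `significant`, `pattern`
#'   (NA for non-significant proteins).
#' @export
diff_abundance <- function(x, labels, n_branches = 5L, ...) {
  an <- anova_per_protein(x, labels)
  an$p_fdr <- bh_adjust(an$p)
  tk <- tukey_posthoc(x, labels)
  rm_ <- ratio_of_means(x, labels)
  gate <- significance_gate(an$p_fdr, tk, rm_, ...)
  out <- cbind(an[c("protein_id", "F", "p", "p_fdr", "testable")],
               tk[-1], rm_[-1], gate[-1])
  out$pattern <- NA_integer_
  sig_ids <- out$protein_id[out$significant]
  if (length(sig_ids) >= n_branches) {
    prof <- cluster_mean_profiles(subset_proteins(x, sig_ids), labels)
    out$pattern[match(sig_ids, out$protein_id)] <-
      abundance_patterns(prof, n_branches)
  }
  out
}
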