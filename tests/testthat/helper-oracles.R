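# Independent oracles and fixture builders shared across the suite.
# Every oracle is a deliberately naive re-derivation (enumeration, direct
# formula, brute force) kept free of the package's own code paths.

# --- fixtures ---------------------------------------------------------------

toy_matrix <- function(values, day = 1L, genes = NULL) {
  values <- as.matrix(values)
  p <- nrow(values); n <- ncol(values)
  ids <- sprintf("PR%02d", seq_len(p))
  intensity_matrix(values,
                   data.frame(protein_id = ids,
                              gene = genes %||% ids),
                   data.frame(sample_id = sprintf("S%02d_d%d", seq_len(n), day),
                              patient_id = sprintf("S%02d", seq_len(n)),
                              day = day))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

small_cohort <- function(seed = 1L, n_patients = 200L, n_proteins = 200L, ...) {
  generate_cohort(cohort_config(
    n_patients = n_patients, n_proteins = n_proteins,
    block_sizes = c(immunoglobulin = 34L, acute_phase = 20L,
                    cytosolic = 20L, adhesion = 16L),
    seed = seed, ...))
}

test_cohort_config <- function(seed = 1L, ...) {
  cohort_config(n_patients = 400L, n_proteins = 300L,
                block_sizes = c(immunoglobulin = 50L, acute_phase = 30L,
                                cytosolic = 30L, adhesion = 25L),
                seed = seed, ...)
}

# two vectors with an exact sample Pearson correlation r
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); z <- rnorm(n)
  z <- residuals(lm(z ~ x))
  xs <- scale(x)[, 1]; zs <- scale(z)[, 1]
  cbind(x = xs, y = r * xs + sqrt(1 - r^2) * zs)
}

# --- elementary oracles -----------------------------------------------------

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# Pearson correlation between one-hot matrices in the matrix-correlation
# sense (sum of per-class covariances over the pooled normalizer)
mcc_onehot_oracle <- function(truth, pred, levels) {
  T1 <- outer(truth, levels, `==`) * 1
  P1 <- outer(pred, levels, `==`) * 1
  num <- sum(vapply(seq_along(levels), function(k)
    mean(T1[, k] * P1[, k]) - mean(T1[, k]) * mean(P1[, k]), numeric(1)))
  v <- function(M) sum(apply(M, 2, function(col) mean(col^2) - mean(col)^2))
  num / sqrt(v(T1) * v(P1))
}

kneedle_oracle <- function(x, y) {
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))
  d <- yn - xn
  if (max(d) <= 0) return(NA_real_)
  x[which.max(d)]
}

fisher_2x2_oracle <- function(tab) {
  # two-sided p by full hypergeometric enumeration over tables with the
  # observed margins, summing probabilities <= that of the observed table
  m <- rowSums(tab); k <- colSums(tab)
  support <- max(0, k[1] - m[2]):min(m[1], k[1])
  probs <- dhyper(support, m[1], m[2], k[1])
  p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tie-corrected Kruskal-Wallis H computed from first principles
kw_H_oracle <- function(values, labels) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, labels, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

kw_perm_oracle <- function(values, labels, B = 1e5, seed = 1) {
  set.seed(seed)
  H0 <- kw_H_oracle(values, labels)
  hits <- 0L
  for (b in seq_len(B)) {
    if (kw_H_oracle(values, sample(labels)) >= H0 - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# permutation null of Dunn's pairwise |z| with familywise (max-|z|) and raw
# variants; returns raw two-sided permutation p for one pair
dunn_z_oracle <- function(values, labels, a, b) {
  r <- rank(values); N <- length(values)
  ties <- table(values)
  varfac <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  ra <- mean(r[labels == a]); rb <- mean(r[labels == b])
  na <- sum(labels == a); nb <- sum(labels == b)
  (ra - rb) / sqrt(varfac * (1 / na + 1 / nb))
}

# Lance-Williams Ward agglomeration, step by step, on a dissimilarity matrix
ward_lw_oracle <- function(D, k) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  diag(d) <- Inf
  while (length(active) > k) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    ni <- sizes[i]; nj <- sizes[j]
    for (h in seq_along(active)) {
      if (h == i || h == j) next
      nh <- sizes[h]
      d[i, h] <- d[h, i] <-
        ((ni + nh) * d[i, h] + (nj + nh) * d[j, h] - nh * d[i, j]) /
        (ni + nj + nh)
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    active[[j]] <- NULL
    sizes <- sizes[-j]
    d <- d[-j, -j, drop = FALSE]
  }
  labels <- integer(n)
  for (g in seq_along(active)) labels[active[[g]]] <- g
  labels
}

# path-dependent conditional expectation of a single exported tree
tree_expvalue <- function(tr, x, S, node = 1) {
  f <- tr$feature[node]
  if (f < 0) return(tr$values[node, ])
  if ((f + 1) %in% S) {
    child <- if (x[f + 1] <= tr$threshold[node]) tr$left[node] else tr$right[node]
    return(tree_expvalue(tr, x, S, child + 1))
  }
  wl <- tr$cover[tr$left[node] + 1] / tr$cover[node]
  wr <- tr$cover[tr$right[node] + 1] / tr$cover[node]
  wl * tree_expvalue(tr, x, S, tr$left[node] + 1) +
    wr * tree_expvalue(tr, x, S, tr$right[node] + 1)
}

brute_shapley_oracle <- function(tr, x, M) {
  nc <- ncol(tr$values)
  phi <- matrix(0, M, nc)
  for (i in seq_len(M)) {
    others <- setdiff(seq_len(M), i)
    for (k in 0:length(others)) {
      combs <- if (k == 0) matrix(integer(0), 0, 1) else combn(others, k)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (cix in seq_len(ncol(combs))) {
        S <- combs[, cix]
        phi[i, ] <- phi[i, ] +
          w * (tree_expvalue(tr, x, c(S, i)) - tree_expvalue(tr, x, S))
      }
    }
  }
  phi
}
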