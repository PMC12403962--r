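test_that("PCA explained variance matches a direct eigendecomposition", {
  set.seed(21)
  A <- matrix(rnorm(9), 3)
  X <- matrix(rnorm(600), 200) %*% A  # induced 3-variable covariance
  basis <- fit_pca(X, variance_target = 0.99)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(basis$var_frac, (ev / sum(ev))[seq_len(basis$m)],
               tolerance = 1e-10)
  # loadings orthonormal
  G <- crossprod(basis$loadings)
  expect_lt(max(abs(G - diag(basis$m))), 1e-8)
  # sign convention: dominant entry of every component is positive
  doms <- apply(basis$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(doms > 0))
})

test_that("component count is the smallest exceeding the variance target", {
  X <- cbind(rnorm(100, sd = 10), rnorm(100, sd = 1e-4), rnorm(100, sd = 1e-4))
  expect_equal(fit_pca(X, 0.70)$m, 1L)
  expect_error(fit_pca(X, 1), "variance_target")
  b1 <- fit_pca(X, 0.70); b2 <- fit_pca(X, 0.70)
  expect_identical(b1$loadings, b2$loadings)
})

test_that("projection centers by the basis mean and preserves duplicates", {
  set.seed(4)
  X <- matrix(rnorm(500), 50)
  basis <- fit_pca(X, 0.9)
  expect_lt(max(abs(project_pca(matrix(basis$center, 1), basis))), 1e-12)
  dup <- X[c(3, 3), , drop = FALSE]
  sc <- project_pca(dup, basis)
  expect_identical(sc[1, ], sc[2, ])
  expect_error(project_pca(X[, 1:5], basis), "dimension mismatch")
  # retained variance equals the top-m eigenvalues of the covariance
  sc_all <- project_pca(X, basis)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(apply(sc_all, 2, var)), ev[seq_len(basis$m)],
               tolerance = 1e-8)
})

test_that("k-means recovers the exhaustively optimal 1-D two-cluster split", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  km <- fit_kmeans(x, 2, seed = 1L, n_init = 5L)
  expect_equal(sort(km$centroids[, 1]), c(0.5, 10.5))
  expect_equal(km$tot_withinss, 1)  # best of all 2-partitions
  expect_identical(km$labels, fit_kmeans(x, 2, seed = 1L, n_init = 5L)$labels)
})

test_that("k equal to the number of distinct points gives zero SSE", {
  x <- matrix(c(0, 5, 9), ncol = 1)
  expect_equal(fit_kmeans(x, 3, seed = 1L, n_init = 3L)$tot_withinss, 0)
  expect_error(fit_kmeans(x, 4, seed = 1L), "distinct")
})

test_that("diagnostics agree on three well-separated blobs", {
  set.seed(5)
  x <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
             matrix(rnorm(100, 10, 0.3), ncol = 2),
             matrix(rnorm(100, c(0, 20), 0.3), ncol = 2))
  dg <- choose_k(x, 2:6, B_reference = 50L, seed = 1L, n_init = 5L)
  sug <- attr(dg, "suggested")
  expect_equal(sug$silhouette, 3L)
  expect_equal(sug$davies_bouldin, 3L)
  expect_equal(sug$gap, 3L)
  # gap selection is stable in the number of reference draws
  dg2 <- choose_k(x, 2:6, B_reference = 10L, seed = 2L, n_init = 5L)
  dg3 <- choose_k(x, 2:6, B_reference = 100L, seed = 3L, n_init = 5L)
  expect_equal(attr(dg2, "suggested")$gap, attr(dg3, "suggested")$gap)
})

test_that("the gap rule returns k = 1 on a single Gaussian blob", {
  set.seed(6)
  x <- matrix(rnorm(300), ncol = 3)
  dg <- choose_k(x, 2:5, B_reference = 50L, seed = 1L, n_init = 5L)
  expect_equal(attr(dg, "suggested")$gap, 1L)
  expect_error(choose_k(matrix(rnorm(10), 5), k_range = 2:6), "below")
})

test_that("silhouette and Davies-Bouldin approach their separation limits", {
  x <- matrix(c(0, 0.001, 100, 100.001), ncol = 1)
  km <- fit_kmeans(x, 2, seed = 1L, n_init = 3L)
  d <- dist(x)
  sil <- mean(cluster::silhouette(km$labels + 1L, d)[, "sil_width"])
  expect_gt(sil, 0.99)
  expect_lt(davies_bouldin(x, km$labels), 1e-4)
})

test_that("severity relabelling orders clusters by decreasing median SOFA", {
  labels <- rep(0:3, c(10, 10, 10, 10))
  sofa <- rep(c(10, 15, 7, 8), c(10, 10, 10, 10))
  map <- relabel_by_severity(labels, sofa)
  # raw medians 10,15,7,8 -> severity order 1,0,3,2
  expect_equal(map, c(1L, 0L, 3L, 2L))
  expect_equal(relabel_by_severity(rep(0:1, c(5, 5)), rep(c(9, 3), c(5, 5))),
               c(0L, 1L))
})

test_that("severity ties go to the smaller cluster first", {
  labels <- rep(0:1, c(98, 16))
  sofa <- c(rep(8, 98), rep(8, 16))
  expect_equal(relabel_by_severity(labels, sofa), c(1L, 0L))
})

test_that("assignment matches a brute-force distance scan", {
  set.seed(7)
  cent <- matrix(rnorm(12), 4)
  model <- list(centroids = cent, label_map = c(2L, 0L, 3L, 1L))
  sc <- matrix(rnorm(90), 30)
  got <- assign_subtypes(sc, model)
  oracle <- apply(sc, 1, function(v) {
    d <- apply(cent, 1, function(cc) sum((v - cc)^2))
    model$label_map[which.min(d)]
  })
  expect_equal(got, oracle)
  # exact centroid and scale invariance
  expect_equal(assign_subtypes(cent, model), model$label_map)
  expect_equal(assign_subtypes(sc * 3.7, list(centroids = cent * 3.7,
                                              label_map = model$label_map)),
               got)
})

test_that("distance ties resolve to the lowest severity-ordered label", {
  cent <- rbind(c(-1, 0), c(1, 0))
  model <- list(centroids = cent, label_map = c(1L, 0L))
  expect_equal(assign_subtypes(matrix(c(0, 5), 1), model), 0L)
})

test_that("training samples re-assign to their k-means clusters", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  km <- fit_kmeans(x, 2, seed = 3L, n_init = 5L)
  re <- assign_subtypes(x, list(centroids = km$centroids,
                                label_map = c(0L, 1L)))
  expect_equal(re, km$labels)
})

test_that("trajectory tables conserve patients and tally transitions", {
  l1 <- c(A = 0L, B = 0L, C = 1L, D = 1L, E = 1L, F = 2L)
  l4 <- c(A = 0L, B = 1L, C = 1L, D = 1L, E = 2L, F = 2L)
  dead <- c(A = TRUE, B = TRUE, C = FALSE, D = FALSE, E = TRUE, F = FALSE)
  tab <- trajectories(l1, l4, dead)
  expect_equal(sum(tab$n), 6)
  expect_equal(attr(tab, "n_patients"), 6)
  pick <- function(d1, d4, out) tab$n[tab$day1 == d1 & tab$day4 == d4 &
                                        tab$outcome == out]
  expect_equal(pick(0, 0, "deceased"), 1)
  expect_equal(pick(0, 1, "deceased"), 1)
  expect_equal(pick(1, 1, "survived"), 2)
  expect_equal(pick(1, 2, "deceased"), 1)
  expect_equal(pick(2, 2, "survived"), 1)
  # marginals over day 4 and outcome reproduce day-1 sizes
  expect_equal(as.vector(tapply(tab$n, tab$day1, sum)), c(2, 3, 1))
  # everyone staying put gives a diagonal table
  diag_tab <- trajectories(l1, l1, dead)
  expect_true(all(diag_tab$n[diag_tab$day1 != diag_tab$day4] == 0))
  expect_error(trajectories(l1[1:3], l4, dead), "no day-1")
})

test_that("serialized models round-trip through JSON", {
  co <- small_cohort(seed = 10L)
  wide <- aggregate_daily(co$clinical, co$registry)
  sofa <- setNames(wide$sofa, wide$patient_id)
  m <- fit_subtype_model(co$day1, co$day4, sofa, seed = 2L, n_init = 5L)
  path <- tempfile(fileext = ".json")
  write_subtype_model(m, path)
  m2 <- read_subtype_model(path)
  expect_equal(m2$centroids, m$centroids, tolerance = 1e-12)
  expect_equal(m2$label_map, m$label_map)
  expect_equal(unname(m2$params$mean), unname(m$params$mean), tolerance = 1e-12)
  l_orig <- assign_matrix(co$day4, m)
  l_json <- assign_matrix(co$day4, m2)
  expect_identical(l_orig, l_json)
})
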