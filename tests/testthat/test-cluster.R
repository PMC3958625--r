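test_that("k-means recovers two well-separated blobs at the exhaustive optimum", {
  set.seed(1)
  m <- rbind(
    matrix(rnorm(10, mean = 0, sd = 0.2), 5, 2),
    matrix(rnorm(10, mean = 8, sd = 0.2), 5, 2)
  )[sample(10), , drop = FALSE]
  truth <- ifelse(m[, 1] > 4, 1, 2)
  fit <- kmeans_lloyd(m, k = 2, n_restarts = 10, seed = 1)
  expect_equal(match_clusters(truth, fit$assignments)$agreement, 1)
  # small-n exhaustive bipartition oracle confirms the optimum
  m8 <- m[1:8, , drop = FALSE]
  fit8 <- kmeans_lloyd(m8, k = 2, n_restarts = 10, seed = 1)
  expect_equal(fit8$within_sse, exhaustive_min_sse(m8), tolerance = 1e-9)
})

test_that("k-means degenerate cases behave as specified", {
  # n = k distinct points: each its own cluster, zero SSE
  pts <- tibble::tibble(user = letters[1:4], x = c(0, 1, 5, 9), y = c(0, 2, 1, 3))
  fit <- kmeans_lloyd(pts, k = 4, n_restarts = 3, seed = 2)
  expect_equal(sort(unname(fit$assignments)), 1:4)
  expect_equal(fit$within_sse, 0)
  # all points identical, k = 1: centroid is the point
  same <- matrix(2, nrow = 5, ncol = 2)
  fit1 <- kmeans_lloyd(same, k = 1, n_restarts = 1, seed = 1)
  expect_equal(unname(fit1$centroids[1, ]), c(2, 2))
  expect_equal(fit1$within_sse, 0)
  # guards
  expect_error(kmeans_lloyd(same, k = 6), "exceeds")
  expect_error(kmeans_lloyd(matrix(c(1, NA, 2, 3), 2), k = 1), "non-finite")
})

test_that("every logged Lloyd trace is non-increasing and terminates on stable memberships", {
  set.seed(33)
  for (i in 1:10) {
    m <- matrix(rnorm(60), 20, 3)
    fit <- kmeans_lloyd(m, k = 4, n_restarts = 5, seed = i)
    expect_true(fit$converged)
    for (tr in fit$sse_traces) expect_true(all(diff(tr) <= 1e-9))
    # no empty clusters in the final result
    expect_setequal(unique(unname(fit$assignments)), 1:4)
  }
})

test_that("results are deterministic given a seed and stable to restarts", {
  m <- matrix(rnorm(45), 15, 3)
  a <- kmeans_lloyd(m, k = 3, n_restarts = 8, seed = 99)
  b <- kmeans_lloyd(m, k = 3, n_restarts = 8, seed = 99)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$within_sse, b$within_sse)
})

test_that("silhouette separates a correct clustering from a shuffled one", {
  set.seed(7)
  m <- rbind(
    matrix(rnorm(40, 0, 0.5), 20, 2),
    matrix(rnorm(40, 10, 0.5), 20, 2) # separation ~10x the spread
  )
  fit <- kmeans_lloyd(m, k = 2, n_restarts = 5, seed = 7)
  good <- internal_metrics(m, fit)
  expect_gt(good$mean_silhouette, 0.9)
  shuffled <- fit
  shuffled$assignments <- setNames(
    sample(fit$assignments), names(fit$assignments)
  )
  expect_lt(internal_metrics(m, shuffled)$mean_silhouette, good$mean_silhouette)
  # k = 1: silhouette undefined
  expect_true(is.na(internal_metrics(m, kmeans_lloyd(m, k = 1, n_restarts = 1))$mean_silhouette))
})

test_that("cluster profiles min-max normalize means and unit-normalize sums", {
  x <- tibble::tibble(
    user = letters[1:6],
    f1 = c(2, 2, 4, 4, 6, 6),
    f2 = c(1, 0, 0, 1, 0, 1)
  )
  fit <- list(
    assignments = setNames(rep(1:3, each = 2), x$user),
    centroids = matrix(0, 3, 2), k = 3
  )
  class(fit) <- "forum_kmeans"
  # f2's cluster means are all 0.5: constant across clusters, warned about
  expect_warning(prof <- profile_clusters(x, fit, unit_sums = TRUE), "constant")
  expect_equal(prof$sizes$size, c(2, 2, 2))
  expect_equal(prof$minmax_means$f2, c(0, 0, 0))
  # cluster means (2, 4, 6) -> min-max (0, 0.5, 1)
  expect_equal(prof$minmax_means$f1, c(0, 0.5, 1))
  # member vectors (1,0) + (0,1) sum to (1,1) -> unit (0.7071, 0.7071)
  pref <- tibble::tibble(user = c("a", "b"), s1 = c(1, 0), s2 = c(0, 1))
  fit1 <- list(assignments = setNames(c(1L, 1L), c("a", "b")),
               centroids = matrix(0, 1, 2), k = 1)
  class(fit1) <- "forum_kmeans"
  expect_warning(prof1 <- profile_clusters(pref, fit1, unit_sums = TRUE), "constant")
  expect_equal(unlist(prof1$unit_sums[1, -1], use.names = FALSE),
               c(1, 1) / sqrt(2), tolerance = 1e-9)
  # single cluster: min-max all zero (constant across clusters)
  expect_equal(unlist(prof1$minmax_means[1, -1], use.names = FALSE), c(0, 0))
})

test_that("profiles and recovery metrics are invariant under cluster relabeling", {
  set.seed(12)
  m <- tibble::tibble(user = sprintf("u%02d", 1:12),
                      x = rnorm(12), y = rnorm(12))
  fit <- kmeans_lloyd(m, k = 3, n_restarts = 5, seed = 3)
  relab <- fit
  perm <- c(3L, 1L, 2L)
  relab$assignments <- setNames(perm[fit$assignments], names(fit$assignments))
  relab$centroids <- fit$centroids[order(perm), , drop = FALSE]
  planted <- rep(c("A", "B", "C"), 4)
  expect_equal(
    match_clusters(planted, fit$assignments),
    match_clusters(planted, relab$assignments)
  )
  p1 <- profile_clusters(m, fit)
  p2 <- profile_clusters(m, relab)
  expect_setequal(p1$sizes$size, p2$sizes$size)
})

test_that("partition agreement and ARI behave at the boundaries", {
  a <- rep(1:3, each = 10)
  expect_equal(match_clusters(a, a)$agreement, 1)
  expect_equal(match_clusters(a, a)$ari, 1)
  flip <- a
  flip[1] <- 2L
  expect_equal(match_clusters(a, flip)$agreement, 29 / 30)
  # planted labels may outnumber recovered clusters; the extra class is
  # simply unmatched
  planted7 <- c(rep(letters[1:6], each = 5), "g")
  rec6 <- c(rep(1:6, each = 5), 1L)
  expect_equal(match_clusters(planted7, rec6)$agreement, 30 / 31)
  expect_error(match_clusters(a[1:10], a), "different row sets")
})

test_that("ARI of independent random partitions concentrates near zero", {
  skip_if_not_installed("mclust")
  set.seed(5)
  aris <- replicate(20, {
    a <- sample(1:5, 1000, replace = TRUE)
    b <- sample(1:5, 1000, replace = TRUE)
    # cross-check the in-package ARI against an independent implementation
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
    adjusted_rand_index(a, b)
  })
  expect_true(all(abs(aris) < 0.05))
})

test_that("tidy, glance and augment expose the fit in broom style", {
  pts <- tibble::tibble(user = letters[1:6], x = c(0, 0.1, 0.2, 5, 5.1, 5.2), y = 0)
  fit <- kmeans_lloyd(pts, k = 2, n_restarts = 3, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("cluster", "size", "x", "y") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_true(gl$converged)
  au <- augment(fit, pts)
  expect_equal(nlevels(au$.cluster), 2)
})
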