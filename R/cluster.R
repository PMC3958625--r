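#' From-scratch Lloyd k-means with membership-stability termination
#'
#' Groups user vectors by proximity in Euclidean space. Each restart runs
#' Lloyd iterations — assign every row to the nearest centroid by squared
#' Euclidean distance (ties to the lowest cluster index), recompute centroids
#' as cluster means — and terminates when no membership changes (the
#' within-cluster sum of squares strictly decreases on any change, so
#' termination is guaranteed; `max_iter` is only a safeguard). The first
#' restart uses a deterministic farthest-point heuristic to blunt bad initial
#' centroid placement: the first centroid is the row nearest the grand mean,
#' each next one the row maximizing its distance to the already-chosen set.
#' Remaining restarts draw k distinct rows at random from seed-derived
#' sub-seeds. The best restart by within-cluster SSE wins. A cluster emptied
#' during iteration is reseeded to the row farthest from its assigned
#' centroid, so the final result never contains empty clusters.
#'
#' @param x Tibble whose first column is `user` (see
#'   [normalize_features()]), or a numeric matrix with rownames.
#' @param k Number of clusters (default 6).
#' @param n_restarts Number of restarts (>= 1); restart 1 is the
#'   farthest-point heuristic.
#' @param max_iter Iteration safeguard per restart.
#' @param seed Integer seed making the random restarts reproducible.
#' @param init `"farthest"` (heuristic first restart, default) or
#'   `"random"` (all restarts random).
#' @return Object of class `forum_kmeans`: `assignments` (named integer),
#'   `centroids` (k x d matrix), `within_sse`, `iterations`, `converged`,
#'   `sse_trace` (per-iteration SSE of the winning restart), `sse_traces`
#'   (all restarts), `k`, `n_restarts`.
#' @examples
#' pts <- tibble::tibble(user = letters[1:4], x = c(0, 0.1, 5, 5.1), y = 0)
#' kmeans_lloyd(pts, k = 2, seed = 1)
#' @export
kmeans_lloyd <- function(x, k = 6, n_restarts = 20, max_iter = 100,
                         seed = NULL, init = c("farthest", "random")) {
  init <- match.arg(init)
  if (is.data.frame(x)) {
    m <- as.matrix(x[-1])
    rownames(m) <- x[[1]]
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (any(!is.finite(m))) abort("non-finite values in clustering input")
  n <- nrow(m)
  if (k > n) abort(paste0("k = ", k, " exceeds the number of rows (", n, ")"))
  if (max_iter < 1 || n_restarts < 1) abort("max_iter and n_restarts must be >= 1")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  sub_seeds <- sample.int(.Machine$integer.max, n_restarts)

  best <- NULL
  traces <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    centers <- if (r == 1 && init == "farthest") {
      farthest_point_init(m, k)
    } else {
      set.seed(sub_seeds[r])
      m[sample.int(n, k), , drop = FALSE]
    }
    run <- lloyd_run(m, centers, max_iter)
    traces[[r]] <- run$sse_trace
    if (is.null(best) || run$within_sse < best$within_sse) best <- run
  }

  structure(
    list(
      assignments = setNames(best$assign, rownames(m)),
      centroids = best$centers,
      within_sse = best$within_sse,
      iterations = best$iterations,
      converged = best$converged,
      sse_trace = best$sse_trace,
      sse_traces = traces,
      k = k,
      n_restarts = n_restarts
    ),
    class = "forum_kmeans"
  )
}

# squared Euclidean distances of every row of m to every center (n x k)
dist2_to_centers <- function(m, centers) {
  cross <- m %*% t(centers)
  d2 <- outer(rowSums(m^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(m)), rowSums(centers^2))
  pmax(d2, 0)
}

farthest_point_init <- function(m, k) {
  gm <- colMeans(m)
  d0 <- colSums((t(m) - gm)^2)
  chosen <- which.min(d0) # ties: lowest row index
  if (k > 1) {
    mind <- dist2_to_centers(m, m[chosen, , drop = FALSE])[, 1]
    while (length(chosen) < k) {
      nxt <- which.max(mind)
      chosen <- c(chosen, nxt)
      mind <- pmin(mind, dist2_to_centers(m, m[nxt, , drop = FALSE])[, 1])
    }
  }
  m[chosen, , drop = FALSE]
}

lloyd_run <- function(m, centers, max_iter) {
  n <- nrow(m)
  k <- nrow(centers)
  assign_prev <- rep(0L, n)
  sse_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(m, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # reseed any emptied cluster to the row farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(assign_new))
      if (length(empty) == 0) break
      cur <- d2[cbind(seq_len(n), assign_new)]
      far <- which.max(cur)
      assign_new[far] <- empty[1]
      centers[empty[1], ] <- m[far, ]
      d2 <- dist2_to_centers(m, centers)
    }
    sse_trace <- c(sse_trace, sum(d2[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_prev)) {
      converged <- TRUE
      break
    }
    assign_prev <- assign_new
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(m[assign_new == j, , drop = FALSE])
    }
    if (iter >= max_iter) break
  }
  d2 <- dist2_to_centers(m, centers)
  within_sse <- sum(d2[cbind(seq_len(n), assign_prev)])
  list(
    assign = assign_prev, centers = centers, within_sse = within_sse,
    iterations = iter, converged = converged, sse_trace = sse_trace
  )
}

#' @export
print.forum_kmeans <- function(x, ...) {
  cat(
    "<forum_kmeans> k = ", x$k, ", n = ", length(x$assignments),
    ", within-SSE ", format(x$within_sse, digits = 6),
    ", ", x$iterations, " iterations",
    if (x$converged) " (memberships stable)" else " (hit max_iter)", "\n",
    sep = ""
  )
  cat("sizes:", paste(tabulate(x$assignments, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Internal clustering evaluation metrics
#'
#' Within-cluster SSE (the k-means objective, recomputed from the data) and
#' the mean silhouette width under Euclidean distance. With k = 1 the
#' silhouette is undefined and reported as `NA`.
#'
#' @param x The data the clustering was fit on (tibble with `user` first
#'   column, or matrix).
#' @param result A `forum_kmeans` object.
#' @return One-row tibble: `within_sse`, `mean_silhouette`.
#' @export
internal_metrics <- function(x, result) {
  stopifnot(inherits(result, "forum_kmeans"))
  m <- if (is.data.frame(x)) as.matrix(x[-1]) else as.matrix(x)
  a <- result$assignments
  stopifnot(nrow(m) == length(a))
  d2 <- dist2_to_centers(m, result$centroids)
  sse <- sum(d2[cbind(seq_along(a), a)])
  sil <- if (result$k < 2) {
    NA_real_
  } else {
    mean(cluster::silhouette(as.integer(a), stats::dist(m))[, "sil_width"])
  }
  tibble::tibble(within_sse = sse, mean_silhouette = sil)
}

#' Profile clusters for reporting
#'
#' Summarizes a clustering on the unnormalized feature scale: per-cluster
#' sizes, raw feature means, and min-max normalized means (each feature's
#' cluster means rescaled to span \[0, 1\]; a feature constant across
#' clusters becomes all-zero with a warning). For a source-preference
#' clustering, also sums the member vectors per cluster and unit-normalizes
#' each sum, giving the cluster's aggregate taste.
#'
#' @param x_raw The unnormalized user-by-feature tibble (`user` first).
#' @param result A `forum_kmeans` fit on (a normalization of) the same rows.
#' @param unit_sums Also compute summed-then-unit-normalized cluster vectors
#'   (preference clusterings).
#' @return Object of class `cluster_profile`: list with tibbles `sizes`,
#'   `raw_means`, `minmax_means`, and optionally `unit_sums`.
#' @export
profile_clusters <- function(x_raw, result, unit_sums = FALSE) {
  stopifnot(inherits(result, "forum_kmeans"), is.data.frame(x_raw))
  if (!identical(as.character(x_raw$user), names(result$assignments))) {
    abort("x_raw rows do not match the clustered rows")
  }
  m <- as.matrix(x_raw[-1])
  a <- result$assignments
  k <- result$k
  sizes <- tibble::tibble(cluster = seq_len(k), size = tabulate(a, k))
  raw <- t(vapply(
    seq_len(k),
    function(j) colMeans(m[a == j, , drop = FALSE]),
    numeric(ncol(m))
  ))
  colnames(raw) <- colnames(m)
  rng <- apply(raw, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span < 1e-12
  if (any(const)) {
    warn(paste0(
      "feature(s) constant across cluster means (min-max set to 0): ",
      paste(colnames(raw)[const], collapse = ", ")
    ))
  }
  mm <- sweep(raw, 2, rng[1, ])
  mm <- sweep(mm, 2, ifelse(const, 1, span), "/")
  mm[, const] <- 0
  out <- list(
    sizes = sizes,
    raw_means = dplyr::bind_cols(sizes["cluster"], tibble::as_tibble(raw)),
    minmax_means = dplyr::bind_cols(sizes["cluster"], tibble::as_tibble(mm))
  )
  if (unit_sums) {
    sums <- t(vapply(
      seq_len(k),
      function(j) colSums(m[a == j, , drop = FALSE]),
      numeric(ncol(m))
    ))
    norms <- sqrt(rowSums(sums^2))
    if (any(norms == 0)) {
      warn("cluster(s) with all-zero summed vector left as zeros")
      norms[norms == 0] <- 1
    }
    out$unit_sums <- dplyr::bind_cols(
      sizes["cluster"], tibble::as_tibble(sums / norms)
    )
  }
  structure(out, class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("<cluster_profile> sizes:", paste(x$sizes$size, collapse = " "), "\n")
  print(x$minmax_means)
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Two label vectors over the same elements.
#' @return ARI (1 for identical partitions, ~0 for independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(if (idx == max_idx) 1 else 0)
  (idx - expected) / (max_idx - expected)
}

#' Agreement between planted and recovered clusterings
#'
#' Cluster indices are arbitrary, so accuracy is maximized over all
#' relabelings: for up to 8 recovered clusters every permutation is tried
#' exhaustively. Also reports the adjusted Rand index, which needs no
#' matching.
#'
#' @param planted Named vector of planted labels (names are users), or an
#'   unnamed vector aligned with `recovered`.
#' @param recovered Named integer vector of recovered assignments (e.g.
#'   `fit$assignments`).
#' @return One-row tibble: `agreement` (best-permutation fraction of rows
#'   with matching labels), `ari`, `n`.
#' @export
match_clusters <- function(planted, recovered) {
  if (!is.null(names(planted)) && !is.null(names(recovered))) {
    if (!setequal(names(planted), names(recovered))) {
      abort("planted and recovered cover different row sets")
    }
    planted <- planted[names(recovered)]
  } else if (length(planted) != length(recovered)) {
    abort("planted and recovered cover different row sets")
  }
  p <- as.integer(factor(planted))
  r <- as.integer(factor(recovered))
  kr <- max(r)
  kp <- max(p)
  kk <- max(kr, kp)
  if (kk > 8) abort("exhaustive permutation matching supports at most 8 clusters")
  tab <- table(factor(r, levels = seq_len(kk)), factor(p, levels = seq_len(kk)))
  best <- 0
  for (perm in all_permutations(seq_len(kk))) {
    # recovered cluster j is read as planted label perm[j]
    hits <- sum(tab[cbind(seq_len(kk), perm)])
    if (hits > best) best <- hits
  }
  tibble::tibble(
    agreement = best / length(r),
    ari = adjusted_rand_index(p, r),
    n = length(r)
  )
}

#' @export
tidy.forum_kmeans <- function(x, ...) {
  k <- x$k
  sizes <- tabulate(x$assignments, k)
  cent <- tibble::as_tibble(x$centroids)
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(k), size = sizes),
    cent
  )
}

#' @export
glance.forum_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$assignments),
    within_sse = x$within_sse,
    iterations = x$iterations,
    converged = x$converged,
    n_restarts = x$n_restarts
  )
}

#' @export
#' @param data The tibble the model was fit on (first column `user`).
#' @rdname kmeans_lloyd
augment.forum_kmeans <- function(x, data, ...) {
  stopifnot(identical(as.character(data$user), names(x$assignments)))
  data$.cluster <- factor(unname(x$assignments))
  data
}
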