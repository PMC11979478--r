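#' Fit K-means to patient vectors
#'
#' Standard K-means (best of `n_restarts` random starts by within-cluster
#' sum of squares), deterministic given `seed`.
#'
#' @param vectors A numeric matrix (rows = patients) or `patient_vectors`.
#' @param k Number of clusters (>= 1; at most the number of distinct rows).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 10).
#' @return A `kmeans_model`: list with `k`, `centroids` (k x d), `inertia`,
#'   `labels` (training assignments), `seed`.
#' @export
fit_kmeans <- function(vectors, k, seed = 1L, n_restarts = 10L) {
  x <- as_vector_matrix(vectors)
  if (k < 1) abort("`k` must be >= 1")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the number of distinct vectors (%d)", k, n_distinct))
  }
  fit <- with_seed(derive_seed(seed, "kmeans", k), {
    if (k == 1) {
      ctr <- matrix(colMeans(x), 1, ncol(x))
      list(centers = ctr, cluster = rep(1L, nrow(x)),
           tot.withinss = sum(sweep(x, 2, ctr[1, ])^2))
    } else if (k == n_distinct) {
      # every distinct point is its own centroid (zero inertia)
      ctr <- unique(x)
      list(centers = ctr,
           cluster = match(apply(x, 1, paste, collapse = "\r"),
                           apply(ctr, 1, paste, collapse = "\r")),
           tot.withinss = 0)
    } else {
      stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100L)
    }
  })
  structure(list(k = as.integer(k),
                 centroids = unname(fit$centers),
                 inertia = fit$tot.withinss,
                 labels = as.integer(fit$cluster),
                 seed = as.integer(seed)),
            class = "kmeans_model")
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> k=%d, inertia=%.4g\n", x$k, x$inertia))
  invisible(x)
}

#' Assign vectors to their nearest centroid
#'
#' Euclidean nearest-centroid classification; exact ties go to the lowest
#' cluster index.
#'
#' @param model A `kmeans_model`.
#' @param vectors Matrix or `patient_vectors` with matching dimension.
#' @return Integer labels in `1..k`.
#' @export
assign_clusters <- function(model, vectors) {
  x <- as_vector_matrix(vectors)
  ctr <- model$centroids
  if (ncol(x) != ncol(ctr)) {
    abort(sprintf("vector dimension (%d) does not match centroids (%d)",
                  ncol(x), ncol(ctr)))
  }
  d2 <- outer(rowSums(x^2), rep(1, nrow(ctr))) -
    2 * x %*% t(ctr) +
    outer(rep(1, nrow(x)), rowSums(ctr^2))
  max.col(-d2, ties.method = "first")
}

#' Mean silhouette score
#'
#' Per point, `(b - a) / max(a, b)` with `a` the mean distance to the
#' point's own cluster (excluding itself) and `b` the smallest mean distance
#' to another cluster; singleton points score 0. Returns the mean over all
#' points. Requires at least two non-empty clusters.
#'
#' @param vectors Matrix or `patient_vectors`.
#' @param labels Integer cluster labels.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(vectors, labels) {
  x <- as_vector_matrix(vectors)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) abort("one label per vector required")
  cl <- sort(unique(labels))
  if (length(cl) < 2) abort("silhouette is undefined for a single cluster")
  D <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sizes <- table(factor(labels, levels = cl))
  # mean distance from every point to every cluster
  sums <- rowsum(t(D), labels)                 # clusters x n: per-cluster distance sums
  s_i <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(labels[i])
    n_own <- sizes[[own]]
    if (n_own == 1) { s_i[i] <- 0; next }
    a <- sums[own, i] / (n_own - 1)
    others <- setdiff(as.character(cl), own)
    b <- min(sums[others, i] / as.numeric(sizes[others]))
    s_i[i] <- (b - a) / max(a, b)
  }
  mean(s_i)
}

#' Calinski-Harabasz index
#'
#' The variance-ratio criterion
#' `[trace(B)/(k - 1)] / [trace(W)/(n - k)]`, with `B` and `W` the between-
#' and within-cluster scatter about the global and cluster means.
#'
#' @inheritParams silhouette_score
#' @return Nonnegative scalar.
#' @export
calinski_harabasz <- function(vectors, labels) {
  x <- as_vector_matrix(vectors)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  k <- length(cl)
  n <- nrow(x)
  if (k < 2) abort("Calinski-Harabasz is undefined for a single cluster")
  gm <- colMeans(x)
  trB <- 0; trW <- 0
  for (c in cl) {
    xc <- x[labels == c, , drop = FALSE]
    cm <- colMeans(xc)
    trB <- trB + nrow(xc) * sum((cm - gm)^2)
    trW <- trW + sum(sweep(xc, 2, cm)^2)
  }
  if (trW == 0) abort("zero within-cluster scatter: variance ratio is degenerate (infinite)")
  (trB / (k - 1)) / (trW / (n - k))
}

#' Internal cluster-quality summary
#'
#' @inheritParams silhouette_score
#' @return Tibble with columns metric, value (silhouette and
#'   calinski_harabasz).
#' @export
cluster_quality <- function(vectors, labels) {
  tibble(metric = c("silhouette", "calinski_harabasz"),
         value = c(silhouette_score(vectors, labels),
                   calinski_harabasz(vectors, labels)))
}
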