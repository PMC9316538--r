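#' K-nearest-neighbour distance scores
#'
#' Classical distance-based outlier score: each sample's score is the mean
#' Euclidean distance to its `k` nearest other samples. Points far from the
#' bulk obtain large scores.
#'
#' @param x Numeric matrix of samples in rows (or a `"normalized_batch"`).
#' @param k Number of neighbours, `1 <= k < n`.
#' @return Numeric vector of scores, one per row.
#' @export
knn_score <- function(x, k = 5) {
  if (inherits(x, "normalized_batch")) x <- x$values
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  if (k >= n) stop("k must be smaller than the number of samples")
  d <- unname(as.matrix(stats::dist(x)))
  diag(d) <- Inf
  apply(d, 1, function(row) mean(sort.int(row, partial = k)[seq_len(k)]))
}

#' K-means centroid distance scores
#'
#' Clusters the samples with `stats::kmeans()` and scores each sample by
#' the Euclidean distance to its assigned cluster centroid: samples in the
#' sparse outskirts of every cluster score high. Empty clusters are handled
#' by `kmeans`'s own re-seeding; the fixed `seed` makes the clustering (and
#' hence the scores) reproducible.
#'
#' @param x Numeric matrix of samples in rows (or a `"normalized_batch"`).
#' @param n_clusters Number of clusters, `1 <= n_clusters < n` (default 8).
#' @param seed Integer seed for the centroid initialization.
#' @param nstart Random restarts passed to `stats::kmeans()` (default 5).
#' @return Numeric vector of scores, one per row.
#' @export
kmeans_score <- function(x, n_clusters = 8, seed = 1, nstart = 5) {
  if (inherits(x, "normalized_batch")) x <- x$values
  x <- as.matrix(x)
  n <- nrow(x)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1 || n_clusters >= n)
    stop("n_clusters must satisfy 1 <= n_clusters < n")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = n_clusters, nstart = nstart, iter.max = 100))
  unname(sqrt(rowSums((x - km$centers[km$cluster, , drop = FALSE])^2)))
}
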