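#' Cluster-centroid undersampling of the majority class
#'
#' Balances an imbalanced feature matrix by replacing the majority-class rows
#' with the centroids of a K-means clustering of them, with K equal to the
#' requested post-sampling majority count (default: the minority count, i.e.
#' a fully balanced output). Minority rows pass through untouched and in
#' their original order; the replacement rows are synthetic points in feature
#' space — they correspond to no real sequence, so anything that needs actual
#' windows (motif inspection, per-sequence reporting) must run before
#' resampling, never after.
#'
#' K-means uses Lloyd's algorithm with k-means++ seeding, 10 restarts and
#' 300 iterations, all driven by `seed`, so the result is reproducible.
#'
#' @param features Numeric matrix (rows = samples).
#' @param labels Binary 0/1 vector, both classes present.
#' @param target Desired majority count after resampling; default the
#'   minority count. Must not exceed the majority count.
#' @param seed Integer seed.
#' @return A `resampling_result`: list with `features`, `labels`,
#'   `synthetic` (TRUE for centroid rows), and `seed`. Minority rows come
#'   first, then the centroids.
#' @export
cluster_centroids_undersample <- function(features, labels, target = NULL,
                                          seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  majority <- if (counts[["0"]] >= counts[["1"]]) 0L else 1L
  minority <- 1L - majority
  n_maj <- sum(labels == majority)
  n_min <- sum(labels == minority)
  if (is.null(target)) target <- n_min
  target <- as.integer(target)
  if (target < 1L) stop("target must be positive")
  if (target > n_maj)
    stop(sprintf("target (%d) exceeds majority count (%d)", target, n_maj))

  maj_rows <- features[labels == majority, , drop = FALSE]
  min_rows <- features[labels == minority, , drop = FALSE]
  centroids <- kmeans_centroids(maj_rows, k = target, seed = seed,
                                restarts = 10L, iter_max = 300L)
  colnames(centroids) <- colnames(features)
  rownames(centroids) <- if (!is.null(rownames(features)))
    sprintf("centroid_%d", seq_len(target))

  out_features <- rbind(min_rows, centroids)
  out_labels <- c(rep(minority, n_min), rep(majority, target))
  structure(list(features = out_features,
                 labels = as.integer(out_labels),
                 synthetic = c(rep(FALSE, n_min), rep(TRUE, target)),
                 seed = as.integer(seed)),
            class = "resampling_result")
}

# k-means++ seeding: first center uniform, then each next center sampled
# with probability proportional to squared distance to the nearest chosen
# center. Feeds stats::kmeans (Lloyd) and keeps the best of `restarts` runs.
kmeans_centroids <- function(x, k, seed, restarts = 10L, iter_max = 300L) {
  stopifnot(k >= 1L, k <= nrow(x))
  if (k == nrow(x)) return(x)  # every point its own centroid
  n_distinct <- nrow(unique(x))
  if (k > n_distinct)
    stop(sprintf("k = %d exceeds the %d distinct rows", k, n_distinct))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, k)
    fit <- tryCatch(
      stats::kmeans(x, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = iter_max,
                                       algorithm = "Lloyd"))
      })
    if (is.null(fit) || nrow(fit$centers) < k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce ", k, " clusters")
  unname(best$centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) idx <- sample.int(n, 1L)
    else idx <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling_result: %d rows (%d original minority, %d centroids), seed %d\n",
              nrow(x$features), sum(!x$synthetic), sum(x$synthetic), x$seed))
  invisible(x)
}
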