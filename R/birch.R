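#' Birch clustering of a cell point set
#'
#' Builds a CF (clustering feature) tree over the points in input order with
#' the given subcluster radius threshold and node branching factor, without a
#' global reclustering step: the leaf subclusters are the final clusters and
#' their centroids the exemplars. Each point is then assigned to its nearest
#' exemplar; exemplars that attract no point are dropped. Deterministic for a
#' fixed input order.
#'
#' @param x,y point coordinates in microns.
#' @param threshold subcluster radius threshold in microns (default 100).
#' @param branching node branching factor (default 10).
#' @return object of class `cell_cluster_set`: `K`, `exemplars` (K x 2),
#'   `assignment` (cluster index per point), `size`, `dispersion` (mean
#'   member-exemplar distance per cluster, microns) and `extent` (max
#'   member-exemplar distance per cluster).
#' @export
birch_clusters <- function(x, y, threshold = 100, branching = 10) {
  n <- length(x)
  if (n == 0) stop("empty point set")
  ex <- cpp_birch_exemplars(as.numeric(x), as.numeric(y), threshold, branching)
  nn <- cpp_nearest_index(as.numeric(x), as.numeric(y), ex[, 1], ex[, 2])
  used <- sort(unique(nn$index))
  remap <- integer(nrow(ex))
  remap[used] <- seq_along(used)
  assignment <- remap[nn$index]
  k <- length(used)
  size <- tabulate(assignment, nbins = k)
  fac <- factor(assignment, levels = seq_len(k))
  dispersion <- vapply(split(nn$distance, fac), mean, 1.0)
  extent <- vapply(split(nn$distance, fac), max, 1.0)
  structure(list(K = k, exemplars = ex[used, 1:2, drop = FALSE],
                 assignment = assignment, size = size,
                 dispersion = unname(dispersion), extent = unname(extent)),
            class = "cell_cluster_set")
}

#' @export
print.cell_cluster_set <- function(x, ...) {
  cat(sprintf("<cell_cluster_set> K = %d over %d points\n",
              x$K, length(x$assignment)))
  invisible(x)
}

#' Internal cluster-validity indices of a point partition
#'
#' Ball-Hall: mean over clusters of the mean squared member-centroid
#' distance. Calinski-Harabasz:
#' `[sum_k n_k ||c_k - c||^2 / (K - 1)] / [sum_k sum_i ||x_i - c_k||^2 / (N - K)]`
#' with `c_k` the member centroids and `c` the grand centroid; undefined
#' (`NA`) when `K = 1` or `N = K`.
#'
#' @param x,y point coordinates.
#' @param assignment integer cluster index per point.
#' @return list with `ball_hall` and `calinski_harabasz`.
#' @export
cluster_indices <- function(x, y, assignment) {
  k <- length(unique(assignment))
  n <- length(x)
  cx <- vapply(split(x, assignment), mean, 1.0)
  cy <- vapply(split(y, assignment), mean, 1.0)
  d2 <- (x - cx[as.character(assignment)])^2 + (y - cy[as.character(assignment)])^2
  ball_hall <- mean(vapply(split(d2, assignment), mean, 1.0))
  ch <- if (k == 1 || n == k) {
    NA_real_
  } else {
    nk <- tabulate(factor(assignment, levels = names(cx)))
    gx <- mean(x); gy <- mean(y)
    between <- sum(nk * ((cx - gx)^2 + (cy - gy)^2)) / (k - 1)
    within <- sum(d2) / (n - k)
    if (within == 0) NA_real_ else between / within
  }
  list(ball_hall = ball_hall, calinski_harabasz = ch)
}
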