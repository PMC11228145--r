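#' Density-based clustering (DBSCAN) on a numeric matrix
#'
#' Classic DBSCAN with Euclidean distances: a point with at least
#' `min_samples` neighbours within radius `eps` (itself included) is a core
#' point; clusters are the connected components of core points plus their
#' border points; everything else is noise (label 0).  Points are processed
#' in row order, so labels are deterministic for a given input.
#'
#' The distance matrix is materialised (O(n^2) memory), which is the right
#' trade-off at cohort scale (thousands of rows).
#'
#' @param x numeric matrix (rows = points); no missing values.
#' @param eps neighbourhood radius (> 0).
#' @param min_samples core-point threshold (>= 1), the point itself counts.
#' @return integer vector of labels; 0 marks noise, clusters are 1, 2, ...
#'   in order of first discovery.
#' @export
dbscan_labels <- function(x, eps, min_samples) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("dbscan_labels: x must be complete")
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  if (min_samples < 1) stop("min_samples must be >= 1")
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nbrs <- apply(d <= eps, 1, which, simplify = FALSE)
  core <- vapply(nbrs, length, integer(1)) >= min_samples

  labels <- integer(n)          # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    # BFS over density-reachable points, deterministic row order
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      pt <- queue[1]
      queue <- queue[-1]
      if (!core[pt]) next
      for (nb in nbrs[[pt]]) {
        if (labels[nb] == 0L) labels[nb] <- cl
        if (!visited[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' Radius heuristic for DBSCAN
#'
#' k-distance rule: for each point compute the distance to its k-th nearest
#' neighbour (k = `min_samples`), and return the 90th percentile of those
#' distances -- an elbow proxy that keeps roughly 90% of points inside some
#' core neighbourhood.
#'
#' @param x numeric matrix, complete.
#' @param min_samples the k of the k-distance curve.
#' @return a positive radius.
#' @export
choose_eps <- function(x, min_samples = 10) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  k <- min(min_samples, nrow(x) - 1)
  kdist <- apply(d, 1, function(r) sort(r)[k + 1])  # +1 skips self-distance 0
  eps <- as.numeric(stats::quantile(kdist, 0.9))
  if (eps <= 0) eps <- max(kdist, .Machine$double.eps)
  eps
}
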