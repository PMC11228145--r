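#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' For a score vector z, returns argmin_p ||p - z||^2 subject to p >= 0,
#' sum(p) = 1, via the sorted-threshold algorithm: with z sorted
#' decreasingly, the support size is the largest k with
#' 1 + k z_(k) > sum_{j<=k} z_(j); the threshold is
#' tau = (sum_{j<=k} z_(j) - 1)/k and p = max(z - tau, 0).  Unlike softmax
#' the output can contain exact zeros, which is what makes the attention
#' masks sparse and interpretable.
#'
#' @param z numeric vector, or matrix (projection applied row-wise).
#' @return probability vector/matrix of the same shape.
#' @export
sparsemax <- function(z) {
  if (is.matrix(z)) {
    out <- sparsemax_rows(z)
    dimnames(out) <- dimnames(z)
    return(out)
  }
  sparsemax_vec(z)
}

sparsemax_vec <- function(z) {
  if (any(!is.finite(z))) stop("sparsemax: non-finite input")
  zs <- sort.int(z, decreasing = TRUE)
  css <- cumsum(zs)
  k <- max(which(1 + seq_along(zs) * zs > css))
  tau <- (css[k] - 1) / k
  pmax(z - tau, 0)
}

# vectorised row-wise sparsemax: rows are sorted decreasingly with one
# global order() call, running sums come from a triangular matrix product,
# and the support size per row is the count of indices satisfying the
# threshold condition (which holds exactly for a prefix).
sparsemax_rows <- function(z) {
  if (any(!is.finite(z))) stop("sparsemax: non-finite input")
  b <- nrow(z)
  u <- ncol(z)
  if (u == 1) return(matrix(1, b, 1))
  zt <- t(z)
  ord <- order(rep(seq_len(b), each = u), -as.vector(zt))
  zs <- matrix(as.vector(zt)[ord], b, u, byrow = TRUE)
  tri <- upper.tri(diag(u), diag = TRUE) * 1
  css <- zs %*% tri
  cond <- 1 + mul_row(zs, seq_len(u)) > css
  k <- rowSums(cond)
  tau <- (css[cbind(seq_len(b), k)] - 1) / k
  pmax(z - tau, 0)
}

# Jacobian-vector product of sparsemax at output q applied to upstream
# gradient dq: on the support S = {q > 0}, dz = dq - mean_S(dq); zero off
# support.
sparsemax_backward <- function(q, dq) {
  s <- q > 0
  if (is.matrix(q)) {
    ns <- rowSums(s)
    mean_s <- rowSums(dq * s) / pmax(ns, 1)
    (dq - mean_s) * s
  } else {
    (dq - mean(dq[s])) * s
  }
}
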