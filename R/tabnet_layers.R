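# Internal building blocks of the attentive tabular network: ghost batch
# normalisation and gated-linear-unit (GLU) feature-transformer blocks, each
# with hand-written forward/backward passes.  Gradients are verified against
# finite differences in the test suite.
#
# Activations are laid out features x samples (one patient per column), so
# per-feature parameters (biases, batch-norm scale/shift, normalisation
# statistics) broadcast down columns by R's native vector recycling.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# add a row vector v to every row of matrix m (schema-level helper; the hot
# network path uses the transposed layout instead)
add_row <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)
mul_row <- function(m, v) m * matrix(v, nrow(m), length(v), byrow = TRUE)

ghost_chunks <- function(n, virtual_batch) {
  k <- ceiling(n / virtual_batch)
  lapply(seq_len(k), function(i) {
    seq.int((i - 1) * virtual_batch + 1, min(i * virtual_batch, n))
  })
}

# --- ghost batch norm -------------------------------------------------------
# Training mode normalises each virtual sub-batch (a block of columns) with
# its own statistics (biased variance, as is conventional) and updates
# running statistics; evaluation mode uses the frozen running statistics.
gbn_forward <- function(z, layer, training, virtual_batch) {
  f <- nrow(z)
  if (!training) {
    invstd <- 1 / sqrt(layer$run_var + BN_EPS)
    xhat <- (z - layer$run_mean) * invstd
    return(list(out = xhat * layer$gamma + layer$beta, cache = NULL,
                layer = layer))
  }
  chunks <- ghost_chunks(ncol(z), virtual_batch)
  out <- z
  cache <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    zc <- z[, idx, drop = FALSE]
    m <- length(idx)
    mu <- .rowMeans(zc, f, m)
    va <- .rowMeans(zc * zc, f, m) - mu * mu
    invstd <- 1 / sqrt(va + BN_EPS)
    xhat <- (zc - mu) * invstd
    out[, idx] <- xhat * layer$gamma + layer$beta
    layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * mu
    layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * va
    cache[[ci]] <- list(idx = idx, xhat = xhat, invstd = invstd)
  }
  list(out = out, cache = cache, layer = layer)
}

gbn_backward <- function(cache, dout, layer) {
  dz <- dout
  f <- nrow(dout)
  dgamma <- numeric(f)
  dbeta <- numeric(f)
  for (ch in cache) {
    doc <- dout[, ch$idx, drop = FALSE]
    m <- length(ch$idx)
    dgamma <- dgamma + .rowSums(doc * ch$xhat, f, m)
    dbeta <- dbeta + .rowSums(doc, f, m)
    dxhat <- doc * layer$gamma
    s1 <- .rowSums(dxhat, f, m)
    s2 <- .rowSums(dxhat * ch$xhat, f, m)
    dz[, ch$idx] <- ch$invstd * (dxhat - (ch$xhat * s2 + s1) / m)
  }
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

new_bn <- function(f) {
  list(gamma = rep(1, f), beta = rep(0, f),
       run_mean = rep(0, f), run_var = rep(1, f))
}

xavier <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

new_glu_block <- function(in_dim, width) {
  c(list(W = xavier(in_dim, 2 * width), b = rep(0, 2 * width)),
    new_bn(2 * width))
}

# --- GLU block --------------------------------------------------------------
# affine to doubled width -> ghost BN -> gated linear unit; residual addition
# scaled by sqrt(0.5) from the second block of a transformer onward (the
# first block changes dimensionality, so it carries no residual).
glu_forward <- function(h, blk, training, virtual_batch, first) {
  width <- length(blk$b) / 2
  z <- crossprod(blk$W, h) + blk$b
  bn <- gbn_forward(z, blk, training, virtual_batch)
  u <- bn$out[seq_len(width), , drop = FALSE]
  v <- bn$out[width + seq_len(width), , drop = FALSE]
  sv <- 1 / (1 + exp(-v))
  g <- u * sv
  out <- if (first) g else (h + g) * sqrt(0.5)
  list(out = out, blk = bn$layer,
       cache = list(h = h, bn = bn$cache, u = u, sv = sv, first = first))
}

glu_backward <- function(cache, dout, blk) {
  if (cache$first) {
    dg <- dout
    dh_res <- 0
  } else {
    dg <- dout * sqrt(0.5)
    dh_res <- dout * sqrt(0.5)
  }
  du <- dg * cache$sv
  dv <- dg * cache$u * cache$sv * (1 - cache$sv)
  bb <- gbn_backward(cache$bn, rbind(du, dv), blk)
  dW <- tcrossprod(cache$h, bb$dz)
  db <- .rowSums(bb$dz, nrow(bb$dz), ncol(bb$dz))
  dh <- blk$W %*% bb$dz + dh_res
  list(dh = dh, dW = dW, db = db, dgamma = bb$dgamma, dbeta = bb$dbeta)
}

# --- feature transformer ----------------------------------------------------
# n_shared blocks (parameters shared across steps) followed by
# n_independent step-specific blocks; returns the width-(n_d + n_a) output.
ft_forward <- function(h, shared, indep, training, virtual_batch) {
  caches <- vector("list", length(shared) + length(indep))
  for (i in seq_along(shared)) {
    res <- glu_forward(h, shared[[i]], training, virtual_batch, first = i == 1)
    h <- res$out
    shared[[i]] <- res$blk
    caches[[i]] <- res$cache
  }
  for (i in seq_along(indep)) {
    res <- glu_forward(h, indep[[i]], training, virtual_batch,
                       first = length(shared) == 0 && i == 1)
    h <- res$out
    indep[[i]] <- res$blk
    caches[[length(shared) + i]] <- res$cache
  }
  list(out = h, shared = shared, indep = indep, caches = caches)
}

zero_block_grad <- function(blk) {
  list(W = blk$W * 0, b = blk$b * 0,
       gamma = blk$gamma * 0, beta = blk$beta * 0)
}

# backward through a feature transformer; accumulates into grad lists
ft_backward <- function(caches, dout, shared, indep,
                        g_shared, g_indep) {
  ns <- length(shared)
  blocks <- c(shared, indep)
  for (i in rev(seq_along(blocks))) {
    bb <- glu_backward(caches[[i]], dout, blocks[[i]])
    dout <- bb$dh
    if (i > ns) {
      k <- i - ns
      g_indep[[k]]$W <- g_indep[[k]]$W + bb$dW
      g_indep[[k]]$b <- g_indep[[k]]$b + bb$db
      g_indep[[k]]$gamma <- g_indep[[k]]$gamma + bb$dgamma
      g_indep[[k]]$beta <- g_indep[[k]]$beta + bb$dbeta
    } else {
      g_shared[[i]]$W <- g_shared[[i]]$W + bb$dW
      g_shared[[i]]$b <- g_shared[[i]]$b + bb$db
      g_shared[[i]]$gamma <- g_shared[[i]]$gamma + bb$dgamma
      g_shared[[i]]$beta <- g_shared[[i]]$beta + bb$dbeta
    }
  }
  list(dh = dout, g_shared = g_shared, g_indep = g_indep)
}
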