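#' Configuration of the group-masked attentive tabular network
#'
#' A sequential attentive architecture for tabular regression: at each of
#' `n_steps` decision steps an attentive transformer produces a sparse
#' attention distribution over mask units (sparsemax of prior-scaled
#' scores), the resulting feature mask multiplies the input, a feature
#' transformer (shared + step-specific GLU blocks) processes the masked
#' input, and the rectified decision outputs are summed into the final
#' linear prediction.  A multiplicative prior discourages re-selecting
#' already-attended units (`gamma = 1` forbids re-selecting a fully
#' attended unit); an entropy penalty (`lambda_sparse`) encourages sparse
#' masks.
#'
#' @param n_steps number of decision steps.
#' @param n_d,n_a widths of the decision and attention outputs.
#' @param gamma prior relaxation (>= 1).
#' @param lambda_sparse weight of the mask-entropy sparsity penalty.
#' @param n_shared,n_independent GLU block counts (shared across steps /
#'   step-specific).
#' @param batch,virtual_batch mini-batch and ghost-batch-norm sizes.
#' @param lr Adam learning rate; decayed by `lr_decay` every 10 epochs.
#' @param lr_decay multiplicative decay factor.
#' @param max_epochs,patience training budget and early-stopping patience
#'   (epochs without validation improvement).
#' @param mask_mode `"broadcast"` gives every member column the unit's
#'   attention value; `"split"` divides it by the unit size.
#' @param seed integer seed for initialisation and shuffling.
#' @return A `tabnet_config` list.
#' @export
tabnet_config <- function(n_steps = 4, n_d = 16, n_a = 16, gamma = 1.5,
                          lambda_sparse = 1e-4, n_shared = 2,
                          n_independent = 2, batch = 256,
                          virtual_batch = 128, lr = 2e-2, lr_decay = 0.95,
                          max_epochs = 200, patience = 30,
                          mask_mode = c("broadcast", "split"), seed = 1L) {
  stopifnot(n_steps >= 1, gamma >= 1, n_d >= 1, n_a >= 1,
            lambda_sparse >= 0, n_shared >= 1, n_independent >= 0)
  structure(list(n_steps = as.integer(n_steps), n_d = as.integer(n_d),
                 n_a = as.integer(n_a), gamma = gamma,
                 lambda_sparse = lambda_sparse,
                 n_shared = as.integer(n_shared),
                 n_independent = as.integer(n_independent),
                 batch = as.integer(batch),
                 virtual_batch = as.integer(virtual_batch),
                 lr = lr, lr_decay = lr_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 mask_mode = match.arg(mask_mode),
                 seed = as.integer(seed)),
            class = "tabnet_config")
}

SPARSE_EPS <- 1e-15   # numeric guard inside the entropy term
PRIOR_TOL <- 1e-12    # prior below this excludes the unit from selection

# membership matrix in the configured mask mode (NULL = per-feature path)
mask_matrix <- function(partition, config) {
  if (is.null(partition)) return(NULL)
  G <- partition$G
  if (config$mask_mode == "split") G <- G / rowSums(G)
  G
}

tabnet_init <- function(p, n_units, config) {
  w <- config$n_d + config$n_a
  indep_ft <- function() {
    lapply(seq_len(config$n_independent), function(i) new_glu_block(w, w))
  }
  list(
    shared = lapply(seq_len(config$n_shared), function(i) {
      new_glu_block(if (i == 1) p else w, w)
    }),
    indep = lapply(seq_len(config$n_steps + 1), function(t) indep_ft()),
    att = lapply(seq_len(config$n_steps), function(t) {
      c(list(W = xavier(config$n_a, n_units), b = rep(0, n_units)),
        new_bn(n_units))
    }),
    w_out = xavier(config$n_d, 1),
    b_out = 0
  )
}

# column-wise sparsemax (units x samples layout) restricted to units whose
# prior is still positive; a unit with exhausted prior can never be
# re-selected, and a sample with no active unit left gets an all-zero
# attention column.
sparsemax_active <- function(z, active) {
  if (!all(active)) {
    # an excluded unit gets a score far below any real one, so it can never
    # enter the simplex-projection support
    z[!active] <- -1e10
  }
  q <- t(sparsemax_rows(t(z)))
  dead <- colSums(active) == 0
  if (any(dead)) q[, dead] <- 0
  q
}

# full forward pass on x laid out columns-as-samples (p x batch); with
# keep_cache the returned caches support backward, with want_trace the
# attention trace is assembled (in the public batch x columns orientation)
net_forward <- function(params, x, config, G, training, keep_cache = FALSE,
                        want_trace = TRUE) {
  p <- nrow(x)
  b <- ncol(x)
  n_units <- if (is.null(G)) p else nrow(G)
  vb <- config$virtual_batch

  init <- ft_forward(x, params$shared, params$indep[[1]], training, vb)
  params$shared <- init$shared
  params$indep[[1]] <- init$indep
  a_prev <- init$out[config$n_d + seq_len(config$n_a), , drop = FALSE]

  prior <- matrix(1, n_units, b)
  out_sum <- matrix(0, config$n_d, b)
  ent_sum <- 0
  q_list <- vector("list", config$n_steps)
  m_list <- vector("list", config$n_steps)
  p_list <- vector("list", config$n_steps)
  eta <- matrix(0, b, config$n_steps)
  steps <- if (keep_cache) vector("list", config$n_steps)

  for (t in seq_len(config$n_steps)) {
    att <- params$att[[t]]
    s <- crossprod(att$W, a_prev) + att$b
    bn <- gbn_forward(s, att, training, vb)
    params$att[[t]] <- bn$layer
    sb <- bn$out
    z <- prior * sb
    active <- prior > PRIOR_TOL
    q <- sparsemax_active(z, active)
    M <- if (is.null(G)) q else crossprod(G, q)
    ent_sum <- ent_sum + sum(-q * log(q + SPARSE_EPS))
    prior_new <- prior * (config$gamma - q)

    xm <- x * M
    ft <- ft_forward(xm, params$shared, params$indep[[t + 1]], training, vb)
    params$shared <- ft$shared
    params$indep[[t + 1]] <- ft$indep
    d <- ft$out[seq_len(config$n_d), , drop = FALSE]
    a_new <- ft$out[config$n_d + seq_len(config$n_a), , drop = FALSE]
    drelu <- d > 0
    dr <- d * drelu
    out_sum <- out_sum + dr
    eta[, t] <- colSums(dr)

    if (want_trace) {
      q_list[[t]] <- t(q)
      m_list[[t]] <- t(M)
      p_list[[t]] <- t(prior)
    }
    if (keep_cache) {
      steps[[t]] <- list(a_prev = a_prev, att_bn = bn$cache, sb = sb,
                         P_pre = prior, q = q, ft_caches = ft$caches,
                         drelu = drelu)
    }
    prior <- prior_new
    a_prev <- a_new
  }

  pred <- drop(crossprod(out_sum, params$w_out)) + params$b_out
  sparsity_loss <- ent_sum / (config$n_steps * b)

  trace <- NULL
  if (want_trace) {
    wm <- Reduce(`+`, lapply(seq_len(config$n_steps),
                             function(t) eta[, t] * m_list[[t]]))
    # samples with zero total step strength fall back to equal step weights
    # so aggregate-importance rows still sum to one
    dead <- rowSums(wm) == 0
    if (any(dead)) {
      flat <- Reduce(`+`, m_list)
      wm[dead, ] <- flat[dead, , drop = FALSE]
    }
    m_agg <- wm / pmax(rowSums(wm), .Machine$double.eps)
    trace <- list(q = q_list, M = m_list, prior = p_list, eta = eta,
                  M_agg = m_agg)
  }
  list(pred = pred, trace = trace, sparsity_loss = sparsity_loss,
       params = params,
       cache = if (keep_cache) list(x = x, init_caches = init$caches,
                                    out_sum = out_sum, steps = steps))
}

zero_grads <- function(params) {
  list(shared = lapply(params$shared, zero_block_grad),
       indep = lapply(params$indep, function(ft) lapply(ft, zero_block_grad)),
       att = lapply(params$att, zero_block_grad),
       w_out = params$w_out * 0, b_out = 0)
}

# column-support sparsemax Jacobian-vector product (units x samples layout)
sparsemax_backward_cols <- function(q, dq) {
  s <- q > 0
  ns <- colSums(s)
  mean_s <- colSums(dq * s) / pmax(ns, 1)
  (dq - rep(mean_s, each = nrow(q))) * s
}

# backward pass for loss = mean((pred - y)^2) + lambda_sparse * sparsity
net_backward <- function(params, fwd, y, config, G) {
  cache <- fwd$cache
  b <- length(y)
  g <- zero_grads(params)

  dpred <- 2 * (fwd$pred - y) / b                   # length b
  g$w_out <- cache$out_sum %*% dpred                # n_d x 1
  g$b_out <- sum(dpred)
  d_out_sum <- params$w_out %*% rbind(dpred)        # n_d x b

  d_a_next <- matrix(0, config$n_a, b)
  d_p_carry <- NULL
  lam <- config$lambda_sparse / (config$n_steps * b)

  for (t in rev(seq_len(config$n_steps))) {
    st <- cache$steps[[t]]
    d_h <- rbind(d_out_sum * st$drelu, d_a_next)
    ftb <- ft_backward(st$ft_caches, d_h, params$shared,
                       params$indep[[t + 1]], g$shared, g$indep[[t + 1]])
    g$shared <- ftb$g_shared
    g$indep[[t + 1]] <- ftb$g_indep
    d_m <- ftb$dh * cache$x
    d_q <- if (is.null(G)) d_m else G %*% d_m
    d_q <- d_q - lam * (log(st$q + SPARSE_EPS) + st$q / (st$q + SPARSE_EPS))
    if (!is.null(d_p_carry)) {
      d_q <- d_q - st$P_pre * d_p_carry   # via prior_new = P * (gamma - q)
    }
    dz <- sparsemax_backward_cols(st$q, d_q)
    d_sb <- dz * st$P_pre
    d_p <- dz * st$sb
    if (!is.null(d_p_carry)) d_p <- d_p + d_p_carry * (config$gamma - st$q)
    attb <- gbn_backward(st$att_bn, d_sb, params$att[[t]])
    g$att[[t]]$gamma <- g$att[[t]]$gamma + attb$dgamma
    g$att[[t]]$beta <- g$att[[t]]$beta + attb$dbeta
    g$att[[t]]$W <- g$att[[t]]$W + tcrossprod(st$a_prev, attb$dz)
    g$att[[t]]$b <- g$att[[t]]$b + rowSums(attb$dz)
    d_a_next <- params$att[[t]]$W %*% attb$dz
    d_p_carry <- d_p
  }

  d_h0 <- rbind(matrix(0, config$n_d, b), d_a_next)
  ftb <- ft_backward(cache$init_caches, d_h0, params$shared,
                     params$indep[[1]], g$shared, g$indep[[1]])
  g$shared <- ftb$g_shared
  g$indep[[1]] <- ftb$g_indep
  g
}

TRAINABLE <- c("W", "b", "gamma", "beta")

adam_walk <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(g)) {
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      res <- adam_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- res$p
      m[[nm]] <- res$m
      v[[nm]] <- res$v
    }
    # unnamed lists (block lists) recurse positionally
    if (is.null(names(g))) {
      for (i in seq_along(g)) {
        res <- adam_walk(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
        p[[i]] <- res$p
        m[[i]] <- res$m
        v[[i]] <- res$v
      }
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

adam_state <- function(grads) {
  rapply(grads, function(x) x * 0, how = "replace")
}

#' Fit the group-masked attentive tabular network
#'
#' Minimises mean-squared error plus `lambda_sparse` times the mask-entropy
#' penalty with Adam; inputs are standardised with training statistics
#' (frozen for inference) and the target is internally standardised.
#' Validation MSE is tracked each epoch and the parameters of the best
#' (peak-validation) epoch are restored.  All randomness (initialisation,
#' shuffling) is governed by `config$seed`.
#'
#' @param x,y training predictor matrix (complete) and numeric target.
#' @param x_valid,y_valid disjoint validation split.
#' @param partition a [mask_unit_partition()], or `NULL` for the standard
#'   per-feature attentive network.
#' @param config a [tabnet_config()].
#' @return An object of class `group_tabnet`: fitted parameters, config,
#'   partition, normalisation constants, training `log` (data.frame with
#'   per-epoch train loss and validation MSE) and `best_epoch`.
#' @export
tabnet_fit <- function(x, y, x_valid, y_valid, partition, config = tabnet_config()) {
  x <- as.matrix(x)
  x_valid <- as.matrix(x_valid)
  if (nrow(x) == 0 || nrow(x_valid) == 0) stop("empty training or validation split")
  if (nrow(x) != length(y) || nrow(x_valid) != length(y_valid)) {
    stop("predictor/target length mismatch")
  }
  G <- mask_matrix(partition, config)
  if (!is.null(G) && ncol(G) != ncol(x)) {
    stop("partition covers ", ncol(G), " columns but x has ", ncol(x))
  }

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, stats::sd)
  x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  xs <- mul_row(add_row(x, -x_center), 1 / x_scale)
  xvs <- mul_row(add_row(x_valid, -x_center), 1 / x_scale)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale
  yvs <- (y_valid - y_center) / y_scale
  xvt <- t(xvs)

  set.seed(config$seed)
  n_units <- if (is.null(G)) ncol(x) else nrow(G)
  params <- tabnet_init(ncol(x), n_units, config)
  grads0 <- zero_grads(params)
  mstate <- adam_state(grads0)
  vstate <- adam_state(grads0)

  n <- nrow(xs)
  best <- list(valid = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    valid_mse = numeric(0))
  t_adam <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr * config$lr_decay^((epoch - 1) %/% 10)
    ord <- sample.int(n)
    batch_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1, n)]
      if (length(idx) < 2) next  # a 1-row batch has no batch statistics
      fwd <- net_forward(params, t(xs[idx, , drop = FALSE]), config, G,
                         training = TRUE, keep_cache = TRUE,
                         want_trace = FALSE)
      params <- fwd$params
      mse <- mean((fwd$pred - ys[idx])^2)
      loss <- mse + config$lambda_sparse * fwd$sparsity_loss
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      g <- net_backward(params, fwd, ys[idx], config, G)
      t_adam <- t_adam + 1L
      upd <- adam_walk(params, g, mstate, vstate, lr, t_adam)
      params <- upd$p
      mstate <- upd$m
      vstate <- upd$v
      batch_loss <- batch_loss + loss
      nb <- nb + 1
    }
    vfwd <- net_forward(params, xvt, config, G, training = FALSE,
                        want_trace = FALSE)
    valid_mse <- mean((vfwd$pred - yvs)^2)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = batch_loss / nb,
                                 valid_mse = valid_mse))
    if (valid_mse < best$valid) {
      best <- list(valid = valid_mse, params = params, epoch = epoch)
    }
    if (epoch - best$epoch >= config$patience) break
  }

  structure(list(params = best$params, config = config,
                 partition = partition, G = G,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 log = log, best_epoch = best$epoch,
                 column_names = colnames(x)),
            class = "group_tabnet")
}

#' @export
print.group_tabnet <- function(x, ...) {
  cat("<group_tabnet> ", length(x$x_center), " columns, ",
      x$config$n_steps, " steps, ",
      if (is.null(x$partition)) "per-feature masking"
      else paste0(length(x$partition$units), " mask units"),
      "; best epoch ", x$best_epoch, " (valid MSE ",
      signif(min(x$log$valid_mse) * x$y_scale^2, 5), ")\n", sep = "")
  invisible(x)
}

model_input <- function(object, newdata) {
  x <- if (inherits(newdata, "clinical_table")) model_matrix(newdata)
       else as.matrix(newdata)
  if (ncol(x) != length(object$x_center)) {
    stop("newdata has ", ncol(x), " columns; model expects ",
         length(object$x_center))
  }
  mul_row(add_row(x, -object$x_center), 1 / object$x_scale)
}

#' Predict blood glucose with a fitted attentive network
#' @param object a `group_tabnet`.
#' @param newdata complete [clinical_table()] or numeric matrix.
#' @param ... unused.
#' @return numeric vector of predictions on the original target scale.
#' @export
predict.group_tabnet <- function(object, newdata, ...) {
  xs <- model_input(object, newdata)
  fwd <- net_forward(object$params, t(xs), object$config, object$G,
                     training = FALSE, want_trace = FALSE)
  object$y_center + object$y_scale * fwd$pred
}

#' Per-step masks and aggregate feature importance
#'
#' Runs a forward pass (inference mode) and returns the attention trace:
#' per-step unit attention `q[[i]]` and feature masks `M[[i]]` (all member
#' columns of a unit share one value), the step-strength-weighted,
#' row-normalised aggregate importance `M_agg`, and the mean importance
#' mass per mask unit (summing to 1), suitable for heatmap export.
#'
#' @param model a fitted `group_tabnet`.
#' @param newdata complete [clinical_table()] or matrix.
#' @return list with `q`, `M`, `prior`, `eta`, `M_agg`, `unit_importance`.
#' @export
tabnet_explain <- function(model, newdata) {
  xs <- model_input(model, newdata)
  fwd <- net_forward(model$params, t(xs), model$config, model$G,
                     training = FALSE)
  tr <- fwd$trace
  if (is.null(model$partition)) {
    ui <- colMeans(tr$M_agg)
    names(ui) <- model$column_names
  } else {
    ui <- vapply(model$partition$units, function(u) {
      mean(rowSums(tr$M_agg[, u$member_columns, drop = FALSE]))
    }, numeric(1))
    names(ui) <- unit_ids(model$partition)
  }
  c(tr, list(unit_importance = ui))
}
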