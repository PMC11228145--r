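tiny_setup <- function(gamma = 1.3, n_steps = 3, seed = 7L) {
  sch <- canonical_schema()
  part <- mask_unit_partition(sch)
  cfg <- tabnet_config(n_steps = n_steps, n_d = 4, n_a = 4,
                       n_independent = 1, virtual_batch = 4,
                       lambda_sparse = 1e-2, gamma = gamma, seed = seed)
  G <- glucotab:::mask_matrix(part, cfg)
  set.seed(seed)
  params <- glucotab:::tabnet_init(39L, nrow(G), cfg)
  list(part = part, cfg = cfg, G = G, params = params)
}

test_that("analytic gradients match finite differences everywhere", {
  s <- tiny_setup()
  set.seed(1)
  x <- t(matrix(rnorm(8 * 39), 8))
  y <- rnorm(8)
  fwd <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = TRUE,
                                keep_cache = TRUE, want_trace = FALSE)
  g <- glucotab:::net_backward(s$params, fwd, y, s$cfg, s$G)
  loss <- function(pr) {
    f <- glucotab:::net_forward(pr, x, s$cfg, s$G, training = TRUE,
                                want_trace = FALSE)
    mean((f$pred - y)^2) + s$cfg$lambda_sparse * f$sparsity_loss
  }
  h <- 1e-6
  sites <- list(
    list(\(P) P$att[[2]]$W,         \(P, v) { P$att[[2]]$W <- v; P },
         g$att[[2]]$W),
    list(\(P) P$att[[1]]$beta,      \(P, v) { P$att[[1]]$beta <- v; P },
         g$att[[1]]$beta),
    list(\(P) P$shared[[1]]$W,      \(P, v) { P$shared[[1]]$W <- v; P },
         g$shared[[1]]$W),
    list(\(P) P$shared[[2]]$gamma,  \(P, v) { P$shared[[2]]$gamma <- v; P },
         g$shared[[2]]$gamma),
    list(\(P) P$indep[[1]][[1]]$b,  \(P, v) { P$indep[[1]][[1]]$b <- v; P },
         g$indep[[1]][[1]]$b),
    list(\(P) P$indep[[4]][[1]]$W,  \(P, v) { P$indep[[4]][[1]]$W <- v; P },
         g$indep[[4]][[1]]$W),
    list(\(P) P$w_out,              \(P, v) { P$w_out <- v; P },
         g$w_out))
  set.seed(5)
  for (site in sites) {
    for (i in sample(length(site[[1]](s$params)),
                     min(4, length(site[[1]](s$params))))) {
      cur <- site[[1]](s$params)
      num <- (loss(site[[2]](s$params, replace(cur, i, cur[i] + h))) -
                loss(site[[2]](s$params, replace(cur, i, cur[i] - h)))) /
        (2 * h)
      expect_equal(site[[3]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("default partition groups B, D and appended blocks, covering all columns", {
  sch <- canonical_schema()
  part <- mask_unit_partition(sch)
  expect_equal(colSums(part$G), rep(1, 39), ignore_attr = TRUE)
  sizes <- rowSums(part$G)
  expect_equal(unname(sizes[c("B", "D")]), c(8, 4))
  expect_equal(sum(sizes == 1), length(part$units) - 2L)

  aug <- augment_group_features(
    simulate_table(simulation_config(n_patients = 50, group_missing_prob = 0,
                                     cell_missing_prob = 0,
                                     seed = 3L))$table)
  part2 <- mask_unit_partition(aug$schema)
  expect_equal(unname(rowSums(part2$G)[c("B", "D", "B_grp", "D_grp")]),
               c(8, 4, 8, 4))

  sing <- singleton_partition(sch)
  expect_true(all(rowSums(sing$G) == 1))
  expect_equal(nrow(sing$G), 39L)
})

test_that("attention rows are simplex-valued and masks share unit values exactly", {
  s <- tiny_setup()
  set.seed(2)
  x <- t(matrix(rnorm(64 * 39), 64))
  fwd <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = FALSE)
  for (t in seq_along(fwd$trace$q)) {
    q <- fwd$trace$q[[t]]
    expect_equal(unname(rowSums(q)), rep(1, 64), tolerance = 1e-10)
    expect_true(all(q >= 0))
    M <- fwd$trace$M[[t]]
    for (u in s$part$units) {
      spread <- apply(M[, u$member_columns, drop = FALSE], 1,
                      function(r) max(r) - min(r))
      expect_identical(max(spread), 0)  # exact, not approximate
    }
  }
  expect_equal(unname(rowSums(fwd$trace$M_agg)), rep(1, 64),
               tolerance = 1e-10)
  expect_true(all(fwd$trace$M_agg >= 0))
})

test_that("a single-step model's aggregate importance is its first mask, row-normalised", {
  s <- tiny_setup(n_steps = 1)
  set.seed(4)
  x <- t(matrix(rnorm(32 * 39), 32))
  fwd <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = FALSE)
  m1 <- fwd$trace$M[[1]]
  expect_equal(fwd$trace$M_agg,
               m1 / pmax(rowSums(m1), .Machine$double.eps), tolerance = 1e-12)
})

test_that("evaluation-mode forward passes are deterministic", {
  s <- tiny_setup()
  set.seed(6)
  x <- t(matrix(rnorm(16 * 39), 16))
  f1 <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = FALSE)
  f2 <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = FALSE)
  expect_identical(f1$pred, f2$pred)
  expect_identical(f1$trace$M_agg, f2$trace$M_agg)
})

test_that("with an exhausted prior at gamma = 1 a unit is never re-selected", {
  s <- tiny_setup(gamma = 1, n_steps = 6)
  set.seed(9)
  x <- t(matrix(rnorm(128 * 39), 128))
  fwd <- glucotab:::net_forward(s$params, x, s$cfg, s$G, training = FALSE)
  acc <- matrix(0, 128, nrow(s$G))
  for (t in seq_along(fwd$trace$q)) {
    q <- fwd$trace$q[[t]]
    expect_equal(sum(q[acc >= 1 - 1e-9] > 0), 0L)
    acc <- acc + q
  }
  expect_lte(max(acc), 1 + 1e-9)
})

test_that("grouped forward with singleton units reduces to the per-feature network", {
  sch <- canonical_schema()
  cfg <- tabnet_config(n_d = 8, n_a = 8, virtual_batch = 16, seed = 12L)
  sing <- singleton_partition(sch)
  G <- glucotab:::mask_matrix(sing, cfg)
  set.seed(12)
  params <- glucotab:::tabnet_init(39L, 39L, cfg)
  set.seed(3)
  x <- t(matrix(rnorm(48 * 39), 48))
  grouped <- glucotab:::net_forward(params, x, cfg, G, training = FALSE)
  standard <- glucotab:::net_forward(params, x, cfg, NULL, training = FALSE)
  expect_equal(grouped$pred, standard$pred, tolerance = 1e-12)
  for (t in seq_along(grouped$trace$M)) {
    expect_equal(unname(grouped$trace$M[[t]]), unname(standard$trace$M[[t]]),
                 tolerance = 1e-12)
  }
})

test_that("training learns a planted sparse signal and logs deterministically", {
  fx <- fx_trained()
  model <- fx$model
  sp <- fx$splits
  met <- compute_metrics(sp$test$target, predict(model, sp$test))
  expect_lt(met$mse, stats::var(sp$test$target))

  cfg_small <- tabnet_config(max_epochs = 3, patience = 3, seed = 5L)
  m1 <- tabnet_fit(model_matrix(sp$train), sp$train$target,
                   model_matrix(sp$valid), sp$valid$target,
                   fx$partition, cfg_small)
  m2 <- tabnet_fit(model_matrix(sp$train), sp$train$target,
                   model_matrix(sp$valid), sp$valid$target,
                   fx$partition, cfg_small)
  expect_identical(m1$log, m2$log)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("explanations expose grouped unit importance on the original scale", {
  fx <- fx_trained()
  ex <- tabnet_explain(fx$model, fx$splits$test)
  expect_true(all(ex$M_agg >= 0))
  expect_equal(sum(ex$unit_importance), 1, tolerance = 1e-8)
  # grouped columns share identical importance in every step mask
  bcols <- fx$partition$units[[which(unit_ids(fx$partition) == "B")]]
  for (t in seq_along(ex$M)) {
    expect_identical(max(apply(ex$M[[t]][, bcols$member_columns], 1,
                               function(r) max(r) - min(r))), 0)
  }
})
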