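# Shared fixtures, memoised so expensive objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# moderate synthetic cohort used by several module tests
fx_sim <- function() {
  fixture("sim400", function() {
    simulate_table(simulation_config(n_patients = 400, seed = 101L))
  })
}

# a small trained grouped-mask model on planted B/D signal
fx_trained <- function() {
  fixture("trained_small", function() {
    sim <- simulate_table(simulation_config(
      n_patients = 600, group_missing_prob = 0, cell_missing_prob = 0,
      noise_sd = 0.5, seed = 77L))
    sp <- split_table(sim$table, seed = 7L)
    part <- mask_unit_partition(sim$table$schema)
    cfg <- tabnet_config(max_epochs = 10, patience = 10, seed = 5L)
    model <- tabnet_fit(model_matrix(sp$train), sp$train$target,
                        model_matrix(sp$valid), sp$valid$target, part, cfg)
    list(model = model, splits = sp, partition = part)
  })
}

# brute-force Euclidean projection onto the probability simplex by support
# enumeration: the independent oracle for sparsemax
project_simplex_bf <- function(z) {
  n <- length(z)
  best <- NULL
  best_d <- Inf
  for (mask in seq_len(2^n - 1)) {
    s <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    tau <- (sum(z[s]) - 1) / sum(s)
    p <- pmax(z - tau, 0) * 0
    p[s] <- z[s] - tau
    if (any(p[s] < -1e-12)) next
    if (any(!s & (z - tau) > 1e-12)) next
    p <- pmax(p, 0)
    d <- sum((p - z)^2)
    if (d < best_d) {
      best_d <- d
      best <- p
    }
  }
  best
}
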