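test_that("error metrics match hand computation and algebraic identities", {
  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$n, 3L)

  set.seed(14)
  for (i in 1:20) {
    y <- rnorm(50)
    yh <- rnorm(50)
    mm <- compute_metrics(y, yh)
    expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-12)
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
  expect_error(compute_metrics(1:3, 1:4), "mismatch")
  expect_error(compute_metrics(numeric(0), numeric(0)), "no observations")
})

test_that("splits are sized, disjoint, exhaustive and seed-reproducible", {
  tab <- simulate_table(simulation_config(n_patients = 100, seed = 3L))$table
  sp <- split_table(tab, seed = 11L)
  expect_equal(vapply(sp, n_patients, 1L),
               c(train = 80L, valid = 10L, test = 10L))
  ids <- unlist(lapply(sp, function(s) s$ids))
  expect_setequal(ids, tab$ids)
  expect_equal(anyDuplicated(ids), 0L)

  sp2 <- split_table(tab, seed = 11L)
  expect_identical(sp$train$ids, sp2$train$ids)
  expect_error(split_table(tab, c(1, 0, 0)), "fractions")
  expect_error(split_table(tab, c(0.5, 0.3, 0.2), seed = 1L), NA)
  expect_error(split_table(glucotab:::subset_table(tab, 1:5),
                           c(0.9, 0.05, 0.05)), "empty")
})

small_pipeline_config <- function(seed = 1L, ...) {
  pipeline_config(
    tabnet = tabnet_config(max_epochs = 3, patience = 3),
    imputation_params = list(nrounds = 25),
    perturb = perturb_spec(copies_per_patient = 1),
    robustness_repeats = 3,
    seed = seed, ...)
}

test_that("the full pipeline is deterministic and records its stages", {
  tab <- simulate_table(simulation_config(n_patients = 300, seed = 42L))$table
  cfg <- small_pipeline_config(seed = 2L)
  r1 <- run_pipeline(tab, cfg)
  r2 <- run_pipeline(tab, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$manifest$stage_checksums, r2$manifest$stage_checksums)
  expect_equal(r1$manifest$n_test, 30L)
  expect_equal(r1$manifest$n_columns, 51L)          # 39 + 12 group means
  expect_equal(r1$manifest$n_train, 2 * 240L)      # originals + 1 copy
  expect_true(all(rowSums(r1$importance$M_agg) > 0))
})

test_that("ablation switches change only their own stage", {
  tab <- simulate_table(simulation_config(n_patients = 300, seed = 43L))$table
  full <- run_pipeline(tab, small_pipeline_config(seed = 5L))
  no_aug_s <- run_pipeline(tab, small_pipeline_config(
    seed = 5L, enable_sample_aug = FALSE))
  no_imp <- run_pipeline(tab, small_pipeline_config(
    seed = 5L, enable_imputation = FALSE))
  no_gm <- run_pipeline(tab, small_pipeline_config(
    seed = 5L, enable_group_mask = FALSE))

  cs <- function(r) r$manifest$stage_checksums
  # removing sample augmentation leaves imputation and feature augmentation
  # untouched
  expect_identical(cs(no_aug_s)$completed, cs(full)$completed)
  expect_identical(cs(no_aug_s)$augmented, cs(full)$augmented)
  expect_false(identical(cs(no_aug_s)$train, cs(full)$train))
  # removing imputation changes the completed table
  expect_false(identical(cs(no_imp)$completed, cs(full)$completed))
  # removing group masking changes only the partition
  expect_identical(cs(no_gm)$train, cs(full)$train)
  expect_equal(no_gm$manifest$n_units, 51L)
  expect_gt(full$manifest$n_units, 2L)
  expect_lt(full$manifest$n_units, 51L)
})

test_that("robustness protocol reports perturbed-minus-base deltas", {
  fx <- fx_trained()
  means <- colMeans(model_matrix(fx$splits$train))

  zero <- robustness_eval(fx$model, fx$splits$test,
                          perturb_spec(epsilon_ratio = 0),
                          train_col_means = means, repeats = 2, seed = 1L)
  expect_identical(unname(zero$deltas), c(0, 0, 0))

  rob <- robustness_eval(fx$model, fx$splits$test, perturb_spec(),
                         train_col_means = means, repeats = 4, seed = 2L)
  expect_equal(unname(rob$deltas["mae"]),
               rob$perturbed$mae - rob$base$mae)
  expect_equal(rob$base$mae,
               compute_metrics(fx$splits$test$target,
                               predict(fx$model, fx$splits$test))$mae)
  expect_error(robustness_eval(fx$model, fx$splits$test, perturb_spec(),
                               means, repeats = 0), "repeats")
})
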