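test_that("fill plans start at B1, follow schema order and skip complete columns", {
  sim <- fx_sim()
  cm <- cluster_patients(sim$table)
  plan <- plan_imputation(sim$table, cm)
  expect_equal(plan$order[1], "B1")
  expect_equal(plan$order,
               group_attributes(sim$table$schema, c("B", "C", "D", "E")))
  expect_length(plan$predictor_base, 19L)

  full <- simulate_table(simulation_config(n_patients = 40,
                                           group_missing_prob = 0,
                                           cell_missing_prob = 0,
                                           seed = 3L))$table
  expect_length(plan_imputation(full, cluster_patients(full))$order, 0L)

  # only D2 gappy -> order is exactly D2
  tab <- full
  obs <- tab$observed
  obs[1:5, "D2"] <- FALSE
  vals <- tab$values
  vals[1:5, "D2"] <- NA_real_
  tab2 <- clinical_table(vals, tab$schema, observed = obs,
                         target = tab$target)
  expect_equal(plan_imputation(tab2, cluster_patients(tab2))$order, "D2")
})

test_that("stepwise imputation never alters observed cells and is deterministic", {
  sim <- fx_sim()
  cm <- cluster_patients(sim$table)
  plan <- plan_imputation(sim$table, cm,
                          model_params = list(nrounds = 40), seed = 5L)
  done1 <- impute_stepwise(sim$table, plan, cm)
  expect_true(all(done1$observed))
  expect_identical(done1$values[sim$table$observed],
                   sim$table$values[sim$table$observed])
  expect_identical(unname(done1$imputed), unname(!sim$table$observed))

  done2 <- impute_stepwise(sim$table, plan, cm)
  expect_identical(done1$values, done2$values)

  # idempotence on an already-complete table
  again <- impute_stepwise(done1)
  expect_identical(again$values, done1$values)
})

test_that("a constant column with one gap is filled with the constant", {
  full <- simulate_table(simulation_config(n_patients = 60,
                                           group_missing_prob = 0,
                                           cell_missing_prob = 0,
                                           seed = 21L))$table
  vals <- full$values
  vals[, "D1"] <- 7.25
  obs <- full$observed
  obs[3, "D1"] <- FALSE
  vals[3, "D1"] <- NA_real_
  tab <- clinical_table(vals, full$schema, observed = obs,
                        target = full$target)
  cm <- cluster_patients(tab)
  done <- impute_stepwise(tab, plan_imputation(tab, cm), cm)
  expect_equal(unname(done$values[3, "D1"]), 7.25)
})

test_that("cluster-informed stepwise fill beats column-mean fill", {
  sim <- simulate_table(simulation_config(n_patients = 800, n_clusters = 3,
                                          cluster_sep = 3,
                                          group_missing_prob = 0.3,
                                          seed = 55L))
  cm <- cluster_patients(sim$table)
  plan <- plan_imputation(sim$table, cm,
                          model_params = list(nrounds = 80), seed = 3L)
  step <- impute_stepwise(sim$table, plan, cm)
  base <- mean_fill_baseline(sim$table)
  masked <- !sim$table$observed
  truth <- sim$truth$complete
  rmse_step <- sqrt(mean((step$values[masked] - truth[masked])^2))
  rmse_mean <- sqrt(mean((base$values[masked] - truth[masked])^2))
  expect_lt(rmse_step, rmse_mean)
})

test_that("mean/mode baseline fills with column statistics and flags dead columns", {
  sch <- canonical_schema()
  sim <- simulate_table(simulation_config(n_patients = 3,
                                          group_missing_prob = 0,
                                          cell_missing_prob = 0, seed = 2L))
  vals <- sim$table$values
  vals[, "B1"] <- c(1, 2, NA)
  obs <- !is.na(vals)
  tab <- clinical_table(vals, sch, observed = obs, target = sim$table$target)
  filled <- mean_fill_baseline(tab)
  expect_equal(unname(filled$values[3, "B1"]), 1.5)
  expect_identical(filled$values[, "B2"], sim$table$values[, "B2"])

  vals2 <- sim$table$values
  vals2[, "C2"] <- NA_real_
  tab2 <- clinical_table(vals2, sch, observed = !is.na(vals2),
                         target = sim$table$target)
  expect_error(mean_fill_baseline(tab2), "C2")
})
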