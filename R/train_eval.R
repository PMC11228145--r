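#' Regression error metrics
#'
#' MAE = mean(|y - yhat|), MSE = mean((y - yhat)^2), RMSE = sqrt(MSE).
#' MAE <= RMSE always (Jensen).
#'
#' @param y actual values.
#' @param yhat predictions of equal length.
#' @return A `glucose_metrics` list: `mae`, `mse`, `rmse`, `n`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))  # mae = mse = 2/3
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch: ", length(y),
                                      " vs ", length(yhat))
  if (length(y) == 0) stop("no observations to evaluate")
  err <- y - yhat
  mse <- mean(err^2)
  structure(list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
                 n = length(y)),
            class = "glucose_metrics")
}

#' @export
print.glucose_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4f  MAE %.4f  RMSE %.4f  (n = %d)\n",
              x$mse, x$mae, x$rmse, x$n))
  invisible(x)
}

#' Random train/validation/test split of a clinical table
#'
#' @param table a [clinical_table()].
#' @param fractions positive fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer seed; the same seed reproduces the same index sets.
#' @return list of three [clinical_table()]s: `train`, `valid`, `test`.
#' @export
split_table <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive numbers summing to 1")
  }
  n <- n_patients(table)
  n_train <- floor(n * fractions[1])
  n_valid <- floor(n * fractions[2])
  n_test <- n - n_train - n_valid
  if (min(n_train, n_valid, n_test) < 1) {
    stop("split produces an empty subset (n = ", n, ")")
  }
  set.seed(seed)
  ord <- sample.int(n)
  list(train = subset_table(table, sort(ord[seq_len(n_train)])),
       valid = subset_table(table, sort(ord[n_train + seq_len(n_valid)])),
       test = subset_table(table, sort(ord[n_train + n_valid +
                                             seq_len(n_test)])))
}

#' Full-pipeline configuration with ablation switches
#'
#' @param enable_imputation cluster-informed stepwise imputation (off =
#'   column mean/mode fill).
#' @param enable_sample_aug bounded-perturbation copies of training rows.
#' @param enable_feature_aug appended group-level mean columns.
#' @param enable_group_mask grouped mask units (off = all-singleton
#'   partition, the standard per-feature attentive network).
#' @param fractions train/validation/test fractions.
#' @param feature_groups groups receiving appended mean columns.
#' @param masked_groups groups sharing one attention value.
#' @param perturb a [perturb_spec()] (its seed is overridden from the
#'   master seed).
#' @param tabnet a [tabnet_config()] (its seed likewise).
#' @param imputation_params gradient-boosted-tree settings for
#'   [plan_imputation()].
#' @param robustness_repeats repeats of the test-perturbation protocol.
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(enable_imputation = TRUE,
                            enable_sample_aug = TRUE,
                            enable_feature_aug = TRUE,
                            enable_group_mask = TRUE,
                            fractions = c(0.8, 0.1, 0.1),
                            feature_groups = c("B", "D"),
                            masked_groups = c("B", "D"),
                            perturb = perturb_spec(),
                            tabnet = tabnet_config(),
                            imputation_params = list(),
                            robustness_repeats = 20,
                            seed = 1L) {
  structure(list(enable_imputation = enable_imputation,
                 enable_sample_aug = enable_sample_aug,
                 enable_feature_aug = enable_feature_aug,
                 enable_group_mask = enable_group_mask,
                 fractions = fractions,
                 feature_groups = feature_groups,
                 masked_groups = masked_groups,
                 perturb = perturb, tabnet = tabnet,
                 imputation_params = imputation_params,
                 robustness_repeats = as.integer(robustness_repeats),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed fan-out of the master seed into stage seeds (recorded in manifest)
stage_seeds <- function(seed) {
  list(impute = seed + 11L, split = seed + 23L, sample_aug = seed + 37L,
       tabnet = seed + 51L, robustness = seed + 67L)
}

checksum <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  signif(sum(v) + sum(v * seq_along(v) %% 97), 12)
}

#' Run the full prediction pipeline
#'
#' Stages: impute (or mean-fill) -> append group-level features -> split
#' 80/10/10 -> perturb-augment the training split -> fit the attentive
#' network (peak-validation selection) -> evaluate on the test split.
#' Ablation switches in `config` disable individual stages.
#'
#' @param table a [clinical_table()] with target.
#' @param config a [pipeline_config()].
#' @return list: `metrics` (test-set [compute_metrics()]), `model`,
#'   `importance` ([tabnet_explain()] on the test split), `splits`,
#'   `train_col_means` (for the robustness protocol), `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config()) {
  if (is.null(table$target)) stop("pipeline stage 'input': table has no target")
  seeds <- stage_seeds(config$seed)

  completed <- if (config$enable_imputation) {
    cm <- cluster_patients(table)
    plan <- plan_imputation(table, cm, model_params = config$imputation_params,
                            seed = seeds$impute)
    impute_stepwise(table, plan, cm)
  } else {
    mean_fill_baseline(table)
  }

  augmented <- if (config$enable_feature_aug) {
    augment_group_features(completed,
                           group_augment_spec(config$feature_groups))
  } else {
    completed
  }

  splits <- split_table(augmented, config$fractions, seed = seeds$split)
  train_col_means <- colMeans(splits$train$values)

  train <- splits$train
  if (config$enable_sample_aug) {
    sp <- config$perturb
    sp$seed <- seeds$sample_aug
    train <- augment_samples(train, sp, col_means = train_col_means)
  }

  partition <- if (config$enable_group_mask) {
    mask_unit_partition(augmented$schema, config$masked_groups)
  } else {
    singleton_partition(augmented$schema)
  }

  tn <- config$tabnet
  tn$seed <- seeds$tabnet
  model <- tabnet_fit(model_matrix(train), train$target,
                      model_matrix(splits$valid), splits$valid$target,
                      partition, tn)

  yhat <- predict(model, splits$test)
  metrics <- compute_metrics(splits$test$target, yhat)
  importance <- tabnet_explain(model, splits$test)

  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    flags = config[c("enable_imputation", "enable_sample_aug",
                     "enable_feature_aug", "enable_group_mask")],
    n_input = n_patients(table),
    n_train = n_patients(train), n_valid = n_patients(splits$valid),
    n_test = n_patients(splits$test),
    n_columns = ncol(augmented$values),
    n_units = length(partition$units),
    best_epoch = model$best_epoch,
    stage_checksums = list(completed = checksum(completed$values),
                           augmented = checksum(augmented$values),
                           train = checksum(train$values)))

  list(metrics = metrics, model = model, importance = importance,
       splits = splits, train_col_means = train_col_means,
       manifest = manifest)
}

#' Robustness protocol: metric deltas under bounded test perturbation
#'
#' For each repeat, every test row gets `n_perturb` randomly chosen
#' continuous indicator features shifted by a draw from (-eps_f, eps_f),
#' with eps_f computed from TRAINING column means; the model is re-evaluated
#' and mean metric deltas (perturbed - base) across repeats are reported.
#'
#' @param model a fitted `group_tabnet`.
#' @param test complete test [clinical_table()] with target.
#' @param spec a [perturb_spec()]; `epsilon_ratio = 0` gives exact-zero
#'   deltas.
#' @param train_col_means named training column means for the eps_f bound.
#' @param repeats number of perturbation repeats (>= 1).
#' @param seed integer seed.
#' @return list: `base` and `perturbed` [compute_metrics()] (perturbed =
#'   mean over repeats), `deltas` (named: mae, mse, rmse).
#' @export
robustness_eval <- function(model, test, spec, train_col_means,
                            repeats = 20, seed = 1L) {
  if (repeats < 1) stop("repeats must be >= 1")
  base <- compute_metrics(test$target, predict(model, test))
  elig <- eligible_columns(test$schema, spec)
  eps <- spec$epsilon_ratio * abs(train_col_means[elig])
  set.seed(seed)
  acc <- c(mae = 0, mse = 0, rmse = 0)
  n <- n_patients(test)
  for (r in seq_len(repeats)) {
    vals <- test$values
    for (i in seq_len(n)) {
      feats <- sample(elig, spec$n_perturb)
      vals[i, feats] <- vals[i, feats] +
        stats::runif(spec$n_perturb, -1, 1) * eps[feats]
    }
    m <- compute_metrics(test$target, predict(model, vals))
    acc <- acc + c(m$mae, m$mse, m$rmse)
  }
  pert <- acc / repeats
  list(base = base,
       perturbed = structure(list(mae = pert[["mae"]], mse = pert[["mse"]],
                                  rmse = pert[["rmse"]], n = base$n),
                             class = "glucose_metrics"),
       deltas = c(mae = pert[["mae"]] - base$mae,
                  mse = pert[["mse"]] - base$mse,
                  rmse = pert[["rmse"]] - base$rmse))
}

#' Ablation study over the pipeline's four components
#'
#' Runs the full pipeline and the four single-component removals:
#' `-Imp` (mean fill instead of cluster-informed imputation), `-AugS`
#' (no sample augmentation), `-AugF` (no group-level feature columns),
#' `-GM` (per-feature instead of grouped masking).
#'
#' @param table a [clinical_table()] with target.
#' @param config a [pipeline_config()] for the full arm.
#' @return named list of pipeline results (`full`, `-Imp`, `-AugS`,
#'   `-AugF`, `-GM`).
#' @export
ablation_study <- function(table, config = pipeline_config()) {
  arms <- list(
    full = config,
    `-Imp` = utils::modifyList(config, list(enable_imputation = FALSE)),
    `-AugS` = utils::modifyList(config, list(enable_sample_aug = FALSE)),
    `-AugF` = utils::modifyList(config, list(enable_feature_aug = FALSE)),
    `-GM` = utils::modifyList(config, list(enable_group_mask = FALSE)))
  lapply(arms, function(cf) {
    class(cf) <- "pipeline_config"
    run_pipeline(table, cf)
  })
}
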