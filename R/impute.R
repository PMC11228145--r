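#' Plan the stepwise fill order for missing panels
#'
#' The multi-stage imputation fills one attribute at a time, feeding each
#' completed column into the next column's prediction model.  The default
#' order is schema order over the skippable panels B, C, D, E (B1...E5),
#' starting at the first liver-function indicator; attributes without
#' missing cells are skipped.  The predictor base is the 19 low-missingness
#' clustering features plus the 20 auxiliary cluster-mean columns.
#'
#' @param table a [clinical_table()].
#' @param cluster_model a `patient_clusters` built from this table.
#' @param order_rule `"schema"` (default) or `"missing"` (ascending missing
#'   count, ties broken by schema order).
#' @param model_params gradient-boosted-tree hyperparameters; see
#'   [impute_stepwise()].
#' @param seed integer seed controlling regressor randomness.
#' @return An object of class `imputation_plan`.
#' @export
plan_imputation <- function(table, cluster_model,
                            order_rule = c("schema", "missing"),
                            model_params = list(), seed = 1L) {
  order_rule <- match.arg(order_rule)
  schema <- table$schema
  fillable <- group_attributes(schema, c("B", "C", "D", "E"))
  miss_counts <- colSums(!table$observed[, schema_index(schema, fillable),
                                         drop = FALSE])
  ord <- fillable[miss_counts > 0]
  if (order_rule == "missing") {
    ord <- ord[order(miss_counts[miss_counts > 0])]
  }
  defaults <- list(nrounds = 200, max_leaves = 31, eta = 0.05, subsample = 0.8)
  model_params <- utils::modifyList(defaults, model_params)
  structure(list(order = ord,
                 predictor_base = cluster_model$clustering_features,
                 model_params = model_params,
                 seed = as.integer(seed)),
            class = "imputation_plan")
}

#' @export
print.imputation_plan <- function(x, ...) {
  cat("<imputation_plan> ", length(x$order), " attribute(s) to fill",
      if (length(x$order)) paste0(", starting at ", x$order[1]), "\n", sep = "")
  invisible(x)
}

fit_gbt <- function(x, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = params$eta,
                  max_leaves = params$max_leaves,
                  max_depth = 0,
                  grow_policy = "lossguide",
                  tree_method = "hist",
                  subsample = params$subsample,
                  nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

#' Cluster-informed stepwise imputation
#'
#' Fills missing cells of the skippable panels one attribute at a time.  For
#' each attribute in the plan order, a gradient-boosted tree regressor is
#' fitted on the patients observing it, with predictors = the clustering
#' features (residual gaps median-filled) + the auxiliary cluster-mean
#' columns + all previously completed panel columns; predictions are written
#' into the missing cells, which then serve as known information for the
#' next attribute.  Originally observed cells are never altered.  Any
#' residual gaps outside the panels (cell dropout in the CBC/differential)
#' are median-filled.  Imputed cells are flagged in the `imputed` matrix.
#'
#' @param table a [clinical_table()].
#' @param plan an [plan_imputation()] result (built on demand when `NULL`).
#' @param cluster_model a `patient_clusters` for this table (built on demand
#'   when `NULL`).
#' @return A complete [clinical_table()] (no unobserved cells) with
#'   provenance flags.
#' @export
impute_stepwise <- function(table, plan = NULL, cluster_model = NULL) {
  schema <- table$schema
  if (is.null(cluster_model)) cluster_model <- cluster_patients(table)
  if (is.null(plan)) plan <- plan_imputation(table, cluster_model)

  values <- table$values
  observed <- table$observed
  imputed <- table$imputed

  aux <- cluster_feature_matrix(cluster_model, table)

  # clustering features: median-fill residual gaps (near-complete panels)
  base_idx <- schema_index(schema, plan$predictor_base)
  for (j in base_idx) {
    miss <- !observed[, j]
    if (any(miss)) {
      values[miss, j] <- stats::median(values[observed[, j], j])
      imputed[miss, j] <- TRUE
    }
  }

  completed <- integer(0)
  for (step in seq_along(plan$order)) {
    a <- plan$order[step]
    j <- schema_index(schema, a)
    miss <- !observed[, j]
    if (!any(miss)) next
    predictors <- cbind(values[, c(base_idx, completed), drop = FALSE], aux)
    train_rows <- which(!miss)
    if (length(train_rows) == 0) {
      warning("attribute ", a, " has no observed training rows; ",
              "falling back to cluster-mean fill")
      values[miss, j] <- aux[miss, paste0(a, "_cl")]
    } else if (stats::sd(values[train_rows, j]) == 0) {
      # constant response: regressor degenerates to the constant
      values[miss, j] <- values[train_rows[1], j]
    } else {
      fit <- fit_gbt(predictors[train_rows, , drop = FALSE],
                     values[train_rows, j], plan$model_params,
                     seed = plan$seed + step)
      values[miss, j] <- predict(fit, xgboost::xgb.DMatrix(
        predictors[miss, , drop = FALSE]))
    }
    imputed[miss, j] <- TRUE
    completed <- c(completed, j)
  }

  # safety net: any column still holding gaps (outside panels and base)
  for (j in seq_len(ncol(values))) {
    miss <- is.na(values[, j])
    if (any(miss)) {
      values[miss, j] <- stats::median(values[!miss, j])
      imputed[miss, j] <- TRUE
    }
  }

  clinical_table(values, schema,
                 observed = matrix(TRUE, nrow(values), ncol(values)),
                 target = table$target, ids = table$ids, imputed = imputed)
}

#' Column mean/mode fill baseline
#'
#' The simplistic baseline the stepwise scheme is measured against: numeric
#' gaps become the column mean of observed cells, categorical gaps the
#' column mode.
#'
#' @param table a [clinical_table()].
#' @return A complete [clinical_table()].
#' @export
mean_fill_baseline <- function(table) {
  schema <- table$schema
  att <- schema$attributes
  values <- table$values
  imputed <- table$imputed
  for (j in seq_len(ncol(values))) {
    miss <- !table$observed[, j]
    if (!any(miss)) next
    obs <- values[!miss, j]
    if (length(obs) == 0) stop("column ", att$attribute_id[j],
                               " is entirely missing; mean undefined")
    fill <- if (att$kind[j] == "categorical") {
      as.numeric(names(which.max(table(obs))))
    } else {
      mean(obs)
    }
    values[miss, j] <- fill
    imputed[miss, j] <- TRUE
  }
  clinical_table(values, schema,
                 observed = matrix(TRUE, nrow(values), ncol(values)),
                 target = table$target, ids = table$ids, imputed = imputed)
}
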