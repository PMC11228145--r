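#' Configuration for the synthetic examination-cohort generator
#'
#' The generator emulates the statistical structure the modelling pipeline
#' assumes: latent patient clusters (so cluster-mean information is
#' informative for imputation), the canonical seven-group schema,
#' group-structured missingness (whole test panels skipped per patient, as
#' when a patient omits the lipid profile), and a continuous blood-glucose
#' target driven by a sparse subset of feature groups.
#'
#' @param n_patients number of patients.
#' @param n_clusters number of latent clusters K.
#' @param cluster_sep scale of between-cluster mean offsets (features have
#'   unit within-cluster standard deviation, so `cluster_sep = 3` gives
#'   well-separated clusters).
#' @param signal_groups group ids whose features carry target effect.
#' @param coef_scale standard deviation of the nonzero regression
#'   coefficients.
#' @param noise_sd residual standard deviation of the target.
#' @param group_missing_prob per-patient probability that a whole skippable
#'   panel (groups B--E) is absent.
#' @param cell_missing_prob additional per-cell dropout on indicator columns
#'   (demographics stay complete).
#' @param seed integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 2000, n_clusters = 3,
                              cluster_sep = 3, signal_groups = c("B", "D"),
                              coef_scale = 1, noise_sd = 1,
                              group_missing_prob = 0.3,
                              cell_missing_prob = 0.01, seed = 1L) {
  stopifnot(n_patients >= 1, n_clusters >= 1, cluster_sep >= 0,
            coef_scale >= 0, noise_sd >= 0,
            group_missing_prob >= 0, group_missing_prob <= 1,
            cell_missing_prob >= 0, cell_missing_prob <= 1)
  structure(list(
    n_patients = as.integer(n_patients), n_clusters = as.integer(n_clusters),
    cluster_sep = cluster_sep, signal_groups = signal_groups,
    coef_scale = coef_scale, noise_sd = noise_sd,
    group_missing_prob = group_missing_prob,
    cell_missing_prob = cell_missing_prob, seed = as.integer(seed)
  ), class = "simulation_config")
}

# panels a patient may skip wholesale; A, F, G are near-complete in routine
# examination data
SKIPPABLE_GROUPS <- c("B", "C", "D", "E")

#' Simulate a clinical-like table with known ground truth
#'
#' Per patient: a latent cluster is drawn; numeric indicators are the
#' cluster mean plus unit-variance Gaussian noise; age is truncated-normal,
#' gender Bernoulli(0.5) independent of cluster; the target is a sparse
#' linear function of the `signal_groups` features plus Gaussian noise.
#' Missingness is MAR-by-group: each of groups B--E is masked wholesale with
#' `group_missing_prob`, then indicator cells drop independently with
#' `cell_missing_prob`; demographics stay complete.
#'
#' @param config a [simulation_config()].
#' @param schema a [feature_schema()]; default [canonical_schema()].
#' @return list with `table` (a [clinical_table()] with target), and
#'   `truth`: `clusters` (integer labels), `coefficients` (named, one per
#'   predictor; zero outside the signal groups), `intercept`, and
#'   `complete` (the pre-masking value matrix).
#' @export
simulate_table <- function(config, schema = canonical_schema()) {
  stopifnot(inherits(config, "simulation_config"))
  att <- schema$attributes
  p <- nrow(att)
  n <- config$n_patients
  set.seed(config$seed)

  numeric_idx <- which(att$kind == "numeric" & att$group_id != "A")
  age_idx <- which(att$attribute_id == "A1")
  gender_idx <- which(att$attribute_id == "A2")

  # cluster means for all numeric indicator columns, spherical, scaled
  centers <- matrix(stats::rnorm(config$n_clusters * length(numeric_idx),
                                 sd = config$cluster_sep),
                    config$n_clusters, length(numeric_idx))
  clusters <- sample.int(config$n_clusters, n, replace = TRUE)

  values <- matrix(NA_real_, n, p, dimnames = list(NULL, att$attribute_id))
  values[, numeric_idx] <- centers[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n * length(numeric_idx)), n)
  # age: truncated normal in [20, 90]; gender: fair coin, independent of cluster
  age <- stats::rnorm(n, mean = 50, sd = 12)
  values[, age_idx] <- pmin(pmax(age, 20), 90)
  values[, gender_idx] <- stats::rbinom(n, 1, 0.5)

  coefficients <- stats::setNames(numeric(p), att$attribute_id)
  sig_idx <- intersect(which(att$group_id %in% config$signal_groups),
                       numeric_idx)
  coefficients[sig_idx] <- stats::rnorm(length(sig_idx),
                                        sd = config$coef_scale)
  intercept <- 5.5  # fasting-glucose-like baseline level
  target <- intercept + drop(values %*% coefficients) +
    stats::rnorm(n, sd = config$noise_sd)

  complete <- values
  observed <- matrix(TRUE, n, p, dimnames = dimnames(values))
  for (g in SKIPPABLE_GROUPS) {
    cols <- which(att$group_id == g)
    skip <- stats::runif(n) < config$group_missing_prob
    observed[skip, cols] <- FALSE
  }
  if (config$cell_missing_prob > 0) {
    ind_cols <- which(att$group_id != "A")
    drop_cells <- matrix(stats::runif(n * length(ind_cols)) <
                           config$cell_missing_prob, n)
    observed[, ind_cols][drop_cells] <- FALSE
  }
  values[!observed] <- NA_real_
  table <- clinical_table(values, schema, observed = observed,
                          target = target,
                          ids = sprintf("P%05d", seq_len(n)))
  list(table = table,
       truth = list(clusters = clusters, coefficients = coefficients,
                    intercept = intercept, complete = complete))
}

#' Small deterministic fixture table for worked examples
#'
#' A 16-patient table with hand-checkable missingness: patient 1 misses all
#' of the hepatitis panel (group E), patient 2 all of the lipid profile
#' (group D), and patient 3 a single liver-function cell (B2).  The seed is
#' baked in, so repeated calls are identical.
#'
#' @return A [clinical_table()] with target.
#' @export
simulate_worked_fixture <- function() {
  cfg <- simulation_config(n_patients = 16, n_clusters = 2, cluster_sep = 4,
                           group_missing_prob = 0, cell_missing_prob = 0,
                           noise_sd = 0.5, seed = 20260101L)
  sim <- simulate_table(cfg)
  tab <- sim$table
  att <- tab$schema$attributes
  obs <- tab$observed
  obs[1, att$group_id == "E"] <- FALSE
  obs[2, att$group_id == "D"] <- FALSE
  obs[3, att$attribute_id == "B2"] <- FALSE
  vals <- tab$values
  vals[!obs] <- NA_real_
  clinical_table(vals, tab$schema, observed = obs, target = tab$target,
                 ids = tab$ids)
}
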