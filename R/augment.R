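#' Specification of bounded-perturbation sample augmentation
#'
#' Each augmented copy of a patient perturbs `n_perturb` randomly chosen
#' indicator features f by an additive shift drawn uniformly from
#' (-eps_f, eps_f), where eps_f = `epsilon_ratio` x the (training) column
#' mean of f.  Age and gender are never perturbed.
#'
#' @param n_perturb number of features perturbed per copy (default 10).
#' @param epsilon_ratio half-width as a fraction of the column mean
#'   (default 1/20).
#' @param copies_per_patient augmented copies per patient (default 2).
#' @param eligible attribute ids eligible for perturbation; `NULL` means all
#'   numeric indicator columns (every attribute except age and gender).
#' @param seed integer RNG seed.
#' @return A `perturb_spec` list.
#' @export
perturb_spec <- function(n_perturb = 10, epsilon_ratio = 1 / 20,
                         copies_per_patient = 2, eligible = NULL,
                         seed = 1L) {
  stopifnot(epsilon_ratio >= 0, n_perturb >= 1, copies_per_patient >= 0)
  structure(list(n_perturb = as.integer(n_perturb),
                 epsilon_ratio = epsilon_ratio,
                 copies_per_patient = as.integer(copies_per_patient),
                 eligible = eligible, seed = as.integer(seed)),
            class = "perturb_spec")
}

eligible_columns <- function(schema, spec) {
  att <- schema$attributes
  if (is.null(spec$eligible)) {
    # numeric indicators: exclude demographics and appended group-mean columns
    att$attribute_id[att$kind == "numeric" & att$group_id != "A" &
                       !grepl("_grp$", att$attribute_id)]
  } else {
    spec$eligible
  }
}

#' Per-column perturbation half-widths
#'
#' eps_f = `epsilon_ratio` x the column mean of f, taken in magnitude so the
#' half-width stays a valid width for synthetic columns whose mean is
#' negative (clinical laboratory indicators are positive-valued, where the
#' two definitions coincide).  Means should come from the training split;
#' pass them explicitly (`col_means`) when perturbing held-out data so the
#' bound is the training-time one.
#'
#' @param table a complete [clinical_table()].
#' @param spec a [perturb_spec()].
#' @param col_means optional named numeric vector of training column means.
#' @return named numeric vector of eps_f over eligible columns.
#' @export
perturb_half_widths <- function(table, spec, col_means = NULL) {
  elig <- eligible_columns(table$schema, spec)
  if (is.null(col_means)) col_means <- colMeans(table$values)
  spec$epsilon_ratio * abs(col_means[elig])
}

#' Sample augmentation: originals plus bounded-perturbation copies
#'
#' Output stacks the unmodified input rows followed by
#' `copies_per_patient` perturbed copies of each patient, each copy
#' differing from its source in exactly `n_perturb` cells by strictly less
#' than its eps_f; the target is copied unchanged.
#'
#' @param table a complete [clinical_table()] (post-imputation).
#' @param spec a [perturb_spec()].
#' @param col_means optional training column means for the eps_f bound
#'   (defaults to this table's means).
#' @return A [clinical_table()] with (1 + copies) x n rows; attribute
#'   `source_row` maps each output row to its input row.
#' @export
augment_samples <- function(table, spec, col_means = NULL) {
  if (!all(table$observed)) stop("augment_samples needs a complete table")
  elig <- eligible_columns(table$schema, spec)
  if (spec$n_perturb > length(elig)) {
    stop("n_perturb (", spec$n_perturb, ") exceeds eligible feature count (",
         length(elig), ")")
  }
  n <- n_patients(table)
  if (spec$copies_per_patient == 0) {
    out <- table
    attr(out, "source_row") <- seq_len(n)
    return(out)
  }
  eps <- perturb_half_widths(table, spec, col_means)
  set.seed(spec$seed)
  blocks <- vector("list", spec$copies_per_patient)
  for (cp in seq_len(spec$copies_per_patient)) {
    vals <- table$values
    for (i in seq_len(n)) {
      feats <- sample(elig, spec$n_perturb)
      delta <- stats::runif(spec$n_perturb, -1, 1) * eps[feats]
      vals[i, feats] <- vals[i, feats] + delta
    }
    blocks[[cp]] <- vals
  }
  values <- do.call(rbind, c(list(table$values), blocks))
  reps <- rep(seq_len(n), 1 + spec$copies_per_patient)
  out <- clinical_table(values, table$schema,
                        target = if (!is.null(table$target))
                          table$target[reps],
                        ids = if (!is.null(table$ids)) table$ids[reps])
  attr(out, "source_row") <- reps
  out
}

#' Specification of group-level feature augmentation
#'
#' @param selected_groups group ids whose attributes get appended
#'   cluster-mean columns (default the liver-function and lipid panels,
#'   `c("B","D")`).
#' @param eps,min_samples,standardize DBSCAN parameters for the all-feature
#'   clustering (`eps = NULL` uses the k-distance heuristic).
#' @return A `group_augment_spec` list.
#' @export
group_augment_spec <- function(selected_groups = c("B", "D"), eps = NULL,
                               min_samples = 10, standardize = TRUE) {
  if (!all(selected_groups %in% LETTERS[2:7])) {
    stop("selected_groups must be drawn from B..G")
  }
  structure(list(selected_groups = selected_groups, eps = eps,
                 min_samples = min_samples, standardize = standardize),
            class = "group_augment_spec")
}

#' Feature augmentation: append group-level mean columns
#'
#' Patients are clustered with DBSCAN on *all* predictor columns (z-scored);
#' then, for every attribute of every selected group, one column is appended
#' holding that attribute's mean over the patient's cluster (noise points
#' receive the global mean).  Appended columns are named
#' `<attribute_id>_grp` and registered in the schema under a new group tag
#' `<group>_grp`, so they can form their own mask units.
#'
#' @param table a complete [clinical_table()].
#' @param spec a [group_augment_spec()].
#' @return A [clinical_table()] with the appended columns and updated
#'   schema; the fitted `patient_clusters` is attached as attribute
#'   `"cluster_model"`.
#' @export
augment_group_features <- function(table, spec = group_augment_spec()) {
  if (!all(table$observed)) stop("augment_group_features needs a complete table")
  if (length(spec$selected_groups) == 0) {
    warning("no groups selected; table returned unchanged")
    return(table)
  }
  schema <- table$schema
  model <- cluster_patients(table,
                            clustering_features = schema_ids(schema),
                            eps = spec$eps, min_samples = spec$min_samples,
                            standardize = spec$standardize)
  sel <- group_attributes(schema, spec$selected_groups)
  aux <- cluster_feature_matrix(model, table, target_attributes = sel)
  colnames(aux) <- paste0(sel, "_grp")

  att <- schema$attributes
  src <- att[match(sel, att$attribute_id), ]
  extra <- data.frame(attribute_id = paste0(sel, "_grp"),
                      name = paste0(src$name, "_grp"),
                      group_id = paste0(src$group_id, "_grp"),
                      kind = "numeric", stringsAsFactors = FALSE)
  new_schema <- feature_schema(rbind(att, extra),
                               target_name = schema$target_name)
  out <- clinical_table(cbind(table$values, aux), new_schema,
                        target = table$target, ids = table$ids)
  attr(out, "cluster_model") <- model
  out
}
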