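#' Cluster patients and derive cluster-level mean features
#'
#' Groups patients with DBSCAN on a designated low-missingness feature set
#' (default: demographics + complete blood count + differential, 19
#' attributes on the canonical schema).  Cells missing within the clustering
#' features are filled with the column median *for distance computation
#' only*; columns are z-scored when `standardize` is `TRUE`.  Per-cluster
#' means are then computed for *all* attributes from the original observed
#' cells, falling back to the global observed mean when no cluster member
#' observes an attribute.  Noise points keep the designated noise label (0).
#'
#' @param table a [clinical_table()].
#' @param clustering_features attribute ids used for the distance; default
#'   [default_clustering_features()].
#' @param eps DBSCAN radius; `NULL` selects it by the k-distance heuristic
#'   ([choose_eps()]).
#' @param min_samples DBSCAN core threshold.
#' @param standardize z-score clustering columns before distances.
#' @return An object of class `patient_clusters`: `labels`,
#'   `clustering_features`, `cluster_means` (cluster x attribute),
#'   `global_means`, `params`.
#' @export
cluster_patients <- function(table, clustering_features = NULL, eps = NULL,
                             min_samples = 10, standardize = TRUE) {
  schema <- table$schema
  if (is.null(clustering_features)) {
    clustering_features <- default_clustering_features(schema)
  }
  cf_idx <- schema_index(schema, clustering_features)
  if (min_samples < 1) stop("min_samples must be >= 1")
  obs_frac <- colMeans(table$observed[, cf_idx, drop = FALSE])
  if (any(obs_frac < 0.5)) {
    stop("clustering feature(s) observed for < 50% of patients: ",
         paste(clustering_features[obs_frac < 0.5], collapse = ", "))
  }

  x <- table$values[, cf_idx, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0  # constant columns carry no distance
  }
  if (is.null(eps)) {
    eps <- choose_eps(x, min_samples)
  } else if (!is.finite(eps) || eps <= 0) {
    stop("eps must be > 0")
  }
  labels <- dbscan_labels(x, eps, min_samples)
  if (all(labels == 0L)) {
    warning("all points classified as noise; degenerating to one global cluster")
    labels <- rep(1L, length(labels))
  }

  global_means <- colMeans(table$values, na.rm = TRUE)
  cluster_ids <- sort(unique(labels[labels > 0L]))
  cluster_means <- matrix(NA_real_, length(cluster_ids), ncol(table$values),
                          dimnames = list(cluster_ids, colnames(table$values)))
  for (k in seq_along(cluster_ids)) {
    members <- labels == cluster_ids[k]
    m <- colMeans(table$values[members, , drop = FALSE], na.rm = TRUE)
    unseen <- !is.finite(m)
    m[unseen] <- global_means[unseen]
    cluster_means[k, ] <- m
  }

  structure(list(labels = labels,
                 clustering_features = clustering_features,
                 cluster_means = cluster_means,
                 global_means = global_means,
                 params = list(eps = eps, min_samples = min_samples,
                               standardize = standardize)),
            class = "patient_clusters")
}

#' @export
print.patient_clusters <- function(x, ...) {
  k <- nrow(x$cluster_means)
  cat("<patient_clusters> ", length(x$labels), " patients, ", k,
      " cluster(s), ", sum(x$labels == 0L), " noise point(s); eps = ",
      signif(x$params$eps, 4), "\n", sep = "")
  invisible(x)
}

#' Auxiliary cluster-level feature matrix
#'
#' For each patient and each target attribute, the mean of that attribute
#' over observed values within the patient's cluster (the cluster-level
#' feature used as extra information by stepwise imputation).  Noise points
#' and clusters where no member observes the attribute receive the global
#' observed mean, so the output never contains missing values.  The default
#' target set is the 20 attributes of the skippable panels B, C, D, E.
#'
#' @param model a `patient_clusters` object.
#' @param table the [clinical_table()] the model was built from.
#' @param target_attributes attribute ids to summarise; must be disjoint
#'   from the clustering features for the imputation use-case.
#' @return numeric matrix, patients x length(target_attributes); columns
#'   named `<attribute_id>_cl`.
#' @export
cluster_feature_matrix <- function(model, table, target_attributes = NULL) {
  schema <- table$schema
  if (is.null(target_attributes)) {
    target_attributes <- group_attributes(schema, c("B", "C", "D", "E"))
  }
  idx <- schema_index(schema, target_attributes)
  labels <- model$labels
  out <- matrix(NA_real_, length(labels), length(idx),
                dimnames = list(NULL, paste0(target_attributes, "_cl")))
  cluster_ids <- as.integer(rownames(model$cluster_means))
  row_of <- match(labels, cluster_ids)  # NA for noise
  for (j in seq_along(idx)) {
    col <- model$cluster_means[row_of, idx[j]]
    col[is.na(row_of)] <- model$global_means[idx[j]]
    out[, j] <- col
  }
  stopifnot(!anyNA(out))
  out
}
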