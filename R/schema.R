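#' Feature schema for clinical examination tables
#'
#' A `feature_schema` describes the columns of a patient-by-attribute table:
#' every predictor attribute has a short id (e.g. `"B1"`), a human-readable
#' column name, a clinical group (one letter, `A` demographics through `G`
#' white-cell differential), and a kind (`numeric` or `categorical`).  The
#' regression target (fasting blood glucose) is named separately and belongs
#' to no predictor group.
#'
#' @param attributes data.frame with columns `attribute_id`, `name`,
#'   `group_id`, `kind`.
#' @param target_name name of the target column in files on disk.
#' @return An object of class `feature_schema`.
#' @seealso [canonical_schema()] for the packaged 39-attribute catalogue.
#' @export
feature_schema <- function(attributes, target_name = "blood_glucose") {
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  needed <- c("attribute_id", "name", "group_id", "kind")
  if (!all(needed %in% names(attributes))) {
    stop("schema attributes need columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(attributes$attribute_id)) {
    stop("attribute_ids must be unique")
  }
  if (anyDuplicated(attributes$name)) {
    stop("attribute names must be unique")
  }
  if (!all(attributes$kind %in% c("numeric", "categorical"))) {
    stop("attribute kind must be 'numeric' or 'categorical'")
  }
  if (target_name %in% attributes$name) {
    stop("target column must not be a predictor attribute")
  }
  structure(
    list(attributes = attributes, target_name = target_name),
    class = "feature_schema"
  )
}

#' The canonical seven-group clinical schema
#'
#' Returns the packaged attribute catalogue used throughout: 2 demographic
#' attributes (age, gender) plus 37 numeric medical-test indicators in six
#' panels -- liver function (B, 8), kidney function (C, 3), lipid profile
#' (D, 4), hepatitis-B markers (E, 5), complete blood count (F, 12) and
#' white-cell differential (G, 5) -- with a blood-glucose target.  Gender is
#' the only categorical attribute, integer-coded (male = 1, female = 0).
#'
#' @return A `feature_schema` with 39 predictor attributes.
#' @examples
#' sch <- canonical_schema()
#' table(sch$attributes$group_id)
#' @export
canonical_schema <- function() {
  path <- system.file("extdata", "clinical_schema.json", package = "glucotab")
  if (!nzchar(path)) stop("packaged schema file not found")
  raw <- jsonlite::fromJSON(path)
  feature_schema(raw$attributes, target_name = raw$target_name)
}

#' @export
print.feature_schema <- function(x, ...) {
  grp <- table(x$attributes$group_id)
  cat("<feature_schema> ", nrow(x$attributes), " attributes in ",
      length(grp), " groups (", paste(names(grp), unname(grp), sep = ":",
      collapse = " "), "); target '", x$target_name, "'\n", sep = "")
  invisible(x)
}

schema_ids <- function(schema) schema$attributes$attribute_id
schema_names <- function(schema) schema$attributes$name

#' Attribute ids belonging to given clinical groups
#'
#' @param schema a `feature_schema`.
#' @param groups character vector of group ids (e.g. `c("B", "D")`).
#' @return Character vector of attribute ids, in schema order.
#' @export
group_attributes <- function(schema, groups) {
  a <- schema$attributes
  a$attribute_id[a$group_id %in% groups]
}

#' Default clustering feature set (low-missingness panels)
#'
#' Demographics plus the complete-blood-count and differential panels
#' (groups A, F, G) are near-complete in routine examination data, so they
#' anchor the patient clustering: 19 attributes on the canonical schema.
#'
#' @param schema a `feature_schema`.
#' @return Character vector of attribute ids.
#' @export
default_clustering_features <- function(schema) {
  group_attributes(schema, c("A", "F", "G"))
}

schema_index <- function(schema, attribute_ids) {
  idx <- match(attribute_ids, schema$attributes$attribute_id)
  if (anyNA(idx)) {
    stop("unknown attribute id(s): ",
         paste(attribute_ids[is.na(idx)], collapse = ", "))
  }
  idx
}
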