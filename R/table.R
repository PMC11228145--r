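#' Clinical table: patient x attribute matrix with an explicit missingness mask
#'
#' The central data container.  `values` is a numeric matrix with one column
#' per schema attribute in schema order (categorical columns integer-coded);
#' `observed` is a same-shape logical mask (`TRUE` = measured).  Cells where
#' `observed` is `FALSE` hold `NA` and are never read by downstream numerics.
#' An optional per-patient target vector (blood glucose) and identifier
#' vector (excluded from modelling) may be attached.  `imputed` tracks
#' provenance of cells filled in later by the imputation stage.
#'
#' @param values numeric matrix (patients x attributes).
#' @param schema a [feature_schema()].
#' @param observed logical matrix, same shape as `values`; default derived
#'   from `is.na(values)`.
#' @param target optional numeric vector, one entry per patient.
#' @param ids optional character vector of patient identifiers.
#' @param imputed optional logical matrix flagging imputed cells.
#' @return An object of class `clinical_table`.
#' @export
clinical_table <- function(values, schema, observed = NULL, target = NULL,
                           ids = NULL, imputed = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != nrow(schema$attributes)) {
    stop("values has ", ncol(values), " columns; schema expects ",
         nrow(schema$attributes))
  }
  colnames(values) <- schema$attributes$attribute_id
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed)
  if (!identical(dim(observed), dim(values))) {
    stop("observed mask shape differs from values")
  }
  storage.mode(observed) <- "logical"
  colnames(observed) <- colnames(values)
  # enforce the sentinel: unobserved cells are NA, observed cells are not
  values[!observed] <- NA_real_
  if (anyNA(values[observed])) {
    stop("observed cells must hold finite values")
  }
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (length(target) != nrow(values)) {
      stop("target length ", length(target), " != ", nrow(values), " rows")
    }
  }
  if (!is.null(ids) && length(ids) != nrow(values)) {
    stop("ids length mismatch")
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  structure(
    list(schema = schema, values = values, observed = observed,
         target = target, ids = ids, imputed = imputed),
    class = "clinical_table"
  )
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("<clinical_table> ", nrow(x$values), " patients x ", ncol(x$values),
      " attributes; ", sum(!x$observed), " missing cells",
      if (!is.null(x$target)) "; target attached" else "", "\n", sep = "")
  invisible(x)
}

#' Number of patients in a clinical table
#' @param table a `clinical_table`.
#' @return integer row count.
#' @export
n_patients <- function(table) nrow(table$values)

subset_table <- function(table, rows) {
  clinical_table(table$values[rows, , drop = FALSE], table$schema,
                 observed = table$observed[rows, , drop = FALSE],
                 target = if (!is.null(table$target)) table$target[rows],
                 ids = if (!is.null(table$ids)) table$ids[rows],
                 imputed = table$imputed[rows, , drop = FALSE])
}

#' Read a clinical table from delimited text
#'
#' The file must be comma-delimited with a header row containing every
#' schema attribute name; an id column, a date column and the target column
#' are recognised when present.  Empty cells and the tokens in `na_tokens`
#' become unobserved entries of the missingness mask.  Gender is recoded
#' male = 1 / female = 0 when given as text; a missing gender is an error
#' (demographics are complete in routine examination records).
#'
#' @param path file path.
#' @param schema a [feature_schema()]; default [canonical_schema()].
#' @param na_tokens character tokens treated as missing.
#' @param id_col,date_col header names stored but excluded from modelling.
#' @return A [clinical_table()].
#' @export
load_table <- function(path, schema = canonical_schema(),
                       na_tokens = c("", "NA", "NaN"),
                       id_col = "id", date_col = "date") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(schema_names(schema), names(raw))
  if (length(missing_cols)) {
    stop("file lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  att <- schema$attributes
  values <- matrix(NA_real_, n, nrow(att),
                   dimnames = list(NULL, att$attribute_id))
  for (j in seq_len(nrow(att))) {
    col <- raw[[att$name[j]]]
    miss <- is.na(col) | col %in% na_tokens
    if (att$kind[j] == "categorical") {
      if (any(miss)) stop("missing value in categorical column '",
                          att$name[j], "' (row ", which(miss)[1], ")")
      values[, j] <- decode_gender(col, att$name[j])
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!miss & is.na(num))
      if (length(bad)) {
        stop("non-numeric token '", col[bad[1]], "' in column '",
             att$name[j], "' at row ", bad[1])
      }
      num[miss] <- NA_real_
      values[, j] <- num
    }
  }
  target <- NULL
  if (schema$target_name %in% names(raw)) {
    tv <- raw[[schema$target_name]]
    target <- suppressWarnings(as.numeric(tv))
    bad <- which(!(is.na(tv) | tv %in% na_tokens) & is.na(target))
    if (length(bad)) {
      stop("non-numeric target at row ", bad[1])
    }
  }
  ids <- if (id_col %in% names(raw)) as.character(raw[[id_col]])
  tab <- clinical_table(values, schema, target = target, ids = ids)
  if (date_col %in% names(raw)) attr(tab, "dates") <- raw[[date_col]]
  tab
}

decode_gender <- function(x, colname) {
  low <- tolower(trimws(x))
  out <- rep(NA_real_, length(x))
  out[low %in% c("1", "male", "m")] <- 1
  out[low %in% c("0", "female", "f")] <- 0
  if (anyNA(out)) {
    stop("unrecognised value '", x[which(is.na(out))[1]], "' in categorical column '",
         colname, "'")
  }
  out
}

#' Write a clinical table to CSV
#'
#' Unobserved cells are written as empty fields so that
#' `load_table(write_table(t))` round-trips the missingness mask exactly.
#'
#' @param table a [clinical_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  att <- table$schema$attributes
  out <- as.data.frame(table$values)
  names(out) <- att$name
  if (!is.null(table$ids)) out <- cbind(id = table$ids, out)
  if (!is.null(table$target)) out[[table$schema$target_name]] <- table$target
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarise missingness per attribute and per group
#'
#' Counts unobserved cells per attribute, and per clinical group the number
#' of patients missing the *entire* panel -- the grouped skip pattern typical
#' of examination data, where a patient omits a whole test category.
#'
#' @param table a [clinical_table()].
#' @return A list with `per_attribute` (data.frame: attribute_id, group_id,
#'   missing_count) and `group_all_missing` (named integer vector).
#' @export
missingness_summary <- function(table) {
  att <- table$schema$attributes
  miss <- !table$observed
  per_attribute <- data.frame(
    attribute_id = att$attribute_id,
    group_id = att$group_id,
    missing_count = as.integer(colSums(miss)),
    stringsAsFactors = FALSE
  )
  groups <- sort(unique(att$group_id))
  group_all_missing <- vapply(groups, function(g) {
    cols <- att$group_id == g
    sum(rowSums(miss[, cols, drop = FALSE]) == sum(cols))
  }, integer(1))
  list(per_attribute = per_attribute, group_all_missing = group_all_missing)
}

#' Write a missingness summary as JSON
#' @param summary result of [missingness_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_missingness_json <- function(summary, path) {
  jsonlite::write_json(
    list(per_attribute = summary$per_attribute,
         group_all_missing = as.list(summary$group_all_missing)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model-ready predictor matrix of a complete table
#'
#' @param table a complete [clinical_table()] (no unobserved cells).
#' @return numeric matrix, one column per attribute.
#' @export
model_matrix <- function(table) {
  if (!all(table$observed)) {
    stop("table has unobserved cells; run imputation first")
  }
  table$values
}
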