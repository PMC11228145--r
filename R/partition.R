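#' Partition model-input columns into attention mask units
#'
#' The attentive transformer selects over *units* rather than individual
#' columns: all member columns of one unit share a single attention value,
#' so a whole clinical panel is switched on or off together.  The default
#' partition makes one unit per masked group (liver function B and lipid
#' profile D), one unit per appended group-mean block (`B_grp`, `D_grp`),
#' and a singleton unit for every other column.
#'
#' @param schema a [feature_schema()] describing the model-input columns.
#' @param grouped_groups group ids that form multi-column units; appended
#'   `_grp` blocks form one unit each when `group_grp_blocks` is `TRUE`.
#' @param group_grp_blocks treat each appended group-mean block as a unit.
#' @return An object of class `mask_unit_partition`: `units` (list of
#'   `unit_id` and `member_columns`), and `G` (unit x column binary
#'   membership matrix).
#' @export
mask_unit_partition <- function(schema, grouped_groups = c("B", "D"),
                                group_grp_blocks = TRUE) {
  att <- schema$attributes
  p <- nrow(att)
  grp_blocks <- if (group_grp_blocks) {
    unique(att$group_id[grepl("_grp$", att$group_id)])
  } else {
    character(0)
  }
  multi <- c(grouped_groups, grp_blocks)
  units <- list()
  assigned <- logical(p)
  for (g in multi) {
    cols <- which(att$group_id == g)
    if (length(cols) == 0) next
    units[[length(units) + 1]] <- list(unit_id = g, member_columns = cols)
    assigned[cols] <- TRUE
  }
  for (j in which(!assigned)) {
    units[[length(units) + 1]] <- list(unit_id = att$attribute_id[j],
                                       member_columns = j)
  }
  # order units by first member column so the layout follows the schema
  units <- units[order(vapply(units, function(u) u$member_columns[1], 1L))]
  G <- matrix(0, length(units), p,
              dimnames = list(vapply(units, `[[`, "", "unit_id"),
                              att$attribute_id))
  for (i in seq_along(units)) G[i, units[[i]]$member_columns] <- 1
  structure(list(units = units, G = G), class = "mask_unit_partition")
}

#' All-singleton partition (standard per-feature attention)
#' @param schema a [feature_schema()].
#' @return A `mask_unit_partition` with one unit per column.
#' @export
singleton_partition <- function(schema) {
  mask_unit_partition(schema, grouped_groups = character(0),
                      group_grp_blocks = FALSE)
}

#' @export
print.mask_unit_partition <- function(x, ...) {
  sizes <- vapply(x$units, function(u) length(u$member_columns), 1L)
  cat("<mask_unit_partition> ", length(x$units), " units over ",
      ncol(x$G), " columns (", sum(sizes > 1), " grouped)\n", sep = "")
  invisible(x)
}

#' Unit ids of a partition
#' @param partition a `mask_unit_partition`.
#' @return character vector.
#' @export
unit_ids <- function(partition) rownames(partition$G)
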