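# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_usage <- function(msg) abort(msg, class = "immureg_usage_error")
stop_format <- function(msg) abort(msg, class = "immureg_format_error")

#' Convert a wide feature table to a numeric matrix
#'
#' Wide omics tables in immureg keep the feature identifier in the first
#' column (`gene_id` or `peak_id`) and one column per sample. This helper
#' returns the numeric matrix with feature identifiers as row names.
#'
#' @param tbl A wide tibble (first column identifier, remaining columns
#'   numeric sample values).
#' @return A numeric matrix, features in rows, samples in columns.
#' @export
as_feature_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  ids <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_format("non-numeric values in feature table")
  rownames(m) <- ids
  m
}

#' @rdname as_feature_matrix
#' @param m A numeric matrix with row names.
#' @param id_name Name for the identifier column.
#' @export
as_feature_tibble <- function(m, id_name = "gene_id") {
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  }
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_name := rownames(m)), out)
}

check_no_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_format(sprintf(
      "duplicate %s identifier(s): %s", what,
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  invisible(ids)
}

check_finite <- function(m, what) {
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "non-finite value in %s at row %d, column %d", what, bad[1], bad[2]
    ))
  }
  invisible(m)
}
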