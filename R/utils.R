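# Internal helpers shared across modules.

#' @keywords internal
log2p1 <- function(x) log2(x + 1)

# Signal a classed condition so callers/tests can distinguish failure modes.
stop_emtquad <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "emtquad_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

config_error  <- function(msg) stop_emtquad(msg, "emtquad_config_error")
format_error  <- function(msg) stop_emtquad(msg, "emtquad_format_error")
feature_error <- function(msg) stop_emtquad(msg, "emtquad_missing_feature_error")
degenerate_error   <- function(msg) stop_emtquad(msg, "emtquad_degenerate_error")
insufficient_error <- function(msg) stop_emtquad(msg, "emtquad_insufficient_error")
nonestimable_error <- function(msg) stop_emtquad(msg, "emtquad_nonestimable_error")

#' Validate a sample x feature TPM matrix
#'
#' Checks the invariants every downstream analysis assumes: a numeric matrix
#' with unique, non-empty sample (row) and feature (column) identifiers and
#' finite, non-negative values.
#'
#' @param x numeric matrix, samples in rows, features in columns, both named.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    format_error("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    format_error("expression matrix must have sample row names and feature column names")
  if (anyDuplicated(rownames(x)))
    format_error("duplicate sample ids in expression matrix")
  if (anyDuplicated(colnames(x)))
    format_error("duplicate feature ids in expression matrix")
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    format_error(sprintf(
      "expression matrix has a negative or non-finite value at sample '%s', feature '%s'",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

# Extract named features from an ExpressionMatrix, erroring on absent ids.
get_features <- function(expr, feature_ids) {
  missing <- setdiff(feature_ids, colnames(expr))
  if (length(missing) > 0)
    feature_error(sprintf("feature(s) not found in expression matrix: %s",
                          paste(missing, collapse = ", ")))
  expr[, feature_ids, drop = FALSE]
}

#' Validate a clinical table
#'
#' Requires columns `sample_id`, `time`, `event` with unique sample ids,
#' strictly positive times and a binary (0/1) event indicator.  Additional
#' columns (stage, histology, group labels, stromal scores, ...) pass through.
#'
#' @param x data.frame.
#' @return `x`, invisibly, after validation.
#' @export
validate_clinical_table <- function(x) {
  req <- c("sample_id", "time", "event")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0)
    format_error(sprintf("clinical table missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  if (anyDuplicated(x$sample_id))
    format_error("duplicate sample ids in clinical table")
  if (!is.numeric(x$time) || any(!is.finite(x$time)) || any(x$time <= 0))
    format_error("clinical table 'time' must be finite and > 0")
  if (!all(x$event %in% c(0, 1)))
    format_error("clinical table 'event' must be binary 0/1")
  invisible(x)
}
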