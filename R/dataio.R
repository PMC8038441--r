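# Table input/output.  Matrices and clinical tables travel as TSV (tabs are
# unambiguous in gene identifiers), drug-response and qPCR tables as CSV;
# UTF-8, '.' decimal, header mandatory everywhere.

#' Write / read an expression matrix (TSV)
#'
#' TSV layout: header row `sample_id` followed by feature ids; one row per
#' sample.  Reading validates the ExpressionMatrix invariants and reports the
#' offending cell on failure.
#'
#' @param expr validated expression matrix.
#' @param path file path.
#' @return `read_expression_table` returns the validated matrix.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    format_error("expression TSV must start with a 'sample_id' column")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(col), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, names(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    format_error(sprintf("non-numeric or missing cell at row %d (sample '%s'), column '%s'",
                         bad[1, 1], ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  validate_expression_matrix(num)
  num
}

#' Write / read a clinical table (TSV)
#'
#' Required columns `sample_id`, `time`, `event`; any further columns (stage,
#' histology, stromal scores, group labels) are carried through.
#'
#' @param clinical validated clinical data.frame.
#' @param path file path.
#' @return `read_clinical_table` returns the validated data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical_table(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clinical_table
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_clinical_table(df)
  df
}

#' Write / read a drug-response table (CSV)
#'
#' Columns `cell_line`, `drug`, `ic50`, `ec50` (empty cell = missing value);
#' category columns, when present, are carried through.
#'
#' @param drugs data.frame.
#' @param path file path.
#' @return `read_drug_table` returns the data.frame.
#' @export
write_drug_table <- function(drugs, path) {
  utils::write.csv(drugs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_drug_table
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(c("cell_line", "drug"), names(df))
  if (length(missing) > 0)
    format_error(sprintf("drug table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  if (!any(c("ic50", "ec50") %in% names(df)))
    format_error("drug table needs an 'ic50' or 'ec50' column")
  df
}

#' Write / read a dependency panel (TSV)
#'
#' Long format: `cell_line`, `gene`, `raw_effect`, `control_label`
#' (+ `normalized_effect`, `call` on output panels).
#'
#' @param panel data.frame.
#' @param path file path.
#' @return `read_dependency_table` returns the data.frame.
#' @export
write_dependency_table <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dependency_table
#' @export
read_dependency_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("cell_line", "gene", "raw_effect", "control_label"),
                     names(df))
  if (length(missing) > 0)
    format_error(sprintf("dependency table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  df
}

#' Write / read a qPCR plate (CSV with a reference header line)
#'
#' The first line is `#reference=<sample_id>`, then a CSV with columns
#' `sample_id`, `target`, `role`, `rep1`, `rep2`, ...
#'
#' @param plate a `qpcr_plate`.
#' @param path file path.
#' @return `read_qpcr_plate` returns the plate with its
#'   `reference_sample_id` attribute restored.
#' @export
write_qpcr_plate <- function(plate, path) {
  ref <- attr(plate, "reference_sample_id")
  if (is.null(ref)) format_error("qPCR plate lacks a reference sample")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#reference=%s", ref), con)
  utils::write.csv(as.data.frame(plate), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_plate
#' @export
read_qpcr_plate <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  if (!grepl("^#reference=", first))
    format_error("qPCR plate file must start with '#reference=<sample_id>'")
  ref <- sub("^#reference=", "", first)
  df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
  attr(df, "reference_sample_id") <- ref
  class(df) <- c("qpcr_plate", "data.frame")
  df
}

#' Load and validate a pipeline configuration (YAML or JSON)
#'
#' The config must carry either a `simulate:` block (fields of
#' [sim_config()]) or input paths (`expression`, `clinical`, optionally
#' `drugs`, `dependency`, `qpcr`).  Analysis settings: `feature` (default
#' `ZNF71_KRAB`), `cutoff` (default 1.5), `dependency_threshold` (default
#' -0.5), `drug_metric` (default `ic50`), `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config not found: %s", path))
  cfg <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) config_error(paste("unparseable config:",
                                            conditionMessage(e))))
  if (is.null(cfg$simulate) && is.null(cfg$expression))
    config_error("config must contain a 'simulate' block or an 'expression' path")
  cfg$feature <- cfg$feature %||% "ZNF71_KRAB"
  cfg$cutoff <- cfg$cutoff %||% 1.5
  cfg$dependency_threshold <- cfg$dependency_threshold %||% -0.5
  cfg$drug_metric <- cfg$drug_metric %||% "ic50"
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
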