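# Drug-response categorization, resistant-vs-sensitive differential
# expression, and comparative-threshold qPCR quantification.

#' Ternary drug-response categorization by mean +/- 0.5 SD
#'
#' Categorizes cell lines by one drug-response metric (IC50 or EC50):
#' values strictly greater than mean + 0.5 SD are `resistant`, strictly less
#' than mean - 0.5 SD are `sensitive`, and everything in between (including
#' values exactly at a threshold) is `partial`.  SD is the sample standard
#' deviation (n - 1).  Missing values are excluded from the mean/SD and left
#' uncategorized (`NA`).  The rule is invariant to affine transforms of the
#' metric, so it does not matter whether values arrive on a log scale.
#'
#' @param values numeric vector (NA allowed), at least 3 non-missing.
#' @return character vector of categories aligned to `values`, with the
#'   thresholds attached as attribute `thresholds` (`lower`, `upper`).
#' @export
categorize_response <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3)
    insufficient_error("categorize_response requires >= 3 non-missing values")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  lower <- m - 0.5 * s
  upper <- m + 0.5 * s
  out <- rep(NA_character_, length(values))
  out[ok] <- "partial"
  out[ok & values > upper] <- "resistant"
  out[ok & values < lower] <- "sensitive"
  names(out) <- names(values)
  attr(out, "thresholds") <- c(lower = lower, upper = upper)
  out
}

#' Differential expression between resistant and sensitive cell lines
#'
#' Two-sided t-test per feature on log2(TPM + 1), resistant versus sensitive;
#' partial-response and uncategorized lines are excluded.  Pooled-variance
#' (classical Student) by default; p-values uncorrected by default to match
#' per-gene reporting conventions, with optional Benjamini-Hochberg
#' adjustment.
#'
#' @param expr ExpressionMatrix (cell lines x features, TPM).
#' @param categories character vector of response categories named by cell
#'   line id (as from [categorize_response()]).
#' @param features features to test; default all columns of `expr`.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @param adjust p adjustment method for an extra `p_adj` column
#'   (`"none"` or any [stats::p.adjust()] method).
#' @return data.frame with one row per feature: group means (log2 scale),
#'   difference (resistant - sensitive), t, df, p and a `testable` flag;
#'   features are flagged untestable (all-NA statistics) when either group
#'   has fewer than 2 lines.
#' @export
diff_expr_by_response <- function(expr, categories, features = colnames(expr),
                                  welch = FALSE, adjust = "none") {
  validate_expression_matrix(expr)
  if (is.null(names(categories)))
    format_error("categories must be named by cell line id")
  common <- intersect(rownames(expr), names(categories))
  cats <- categories[common]
  res_ids <- common[!is.na(cats) & cats == "resistant"]
  sen_ids <- common[!is.na(cats) & cats == "sensitive"]
  testable <- length(res_ids) >= 2 && length(sen_ids) >= 2
  logx <- log2p1(get_features(expr, features))
  out <- data.frame(feature = features,
                    n_resistant = length(res_ids),
                    n_sensitive = length(sen_ids),
                    mean_resistant = NA_real_, mean_sensitive = NA_real_,
                    diff = NA_real_, t = NA_real_, df = NA_real_,
                    p = NA_real_, testable = testable,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (testable) {
    for (j in seq_along(features)) {
      xr <- logx[res_ids, j]
      xs <- logx[sen_ids, j]
      out$mean_resistant[j] <- mean(xr)
      out$mean_sensitive[j] <- mean(xs)
      out$diff[j] <- mean(xr) - mean(xs)
      tt <- tryCatch(two_sample_t(xr, xs, pooled = !welch),
                     emtquad_degenerate_error = function(e) NULL)
      if (!is.null(tt)) {
        out$t[j] <- tt$statistic
        out$df[j] <- tt$df
        out$p[j] <- tt$p
      }
    }
  }
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Relative expression by the comparative-threshold (2^-ddCt) method
#'
#' For each sample, replicate Ct values are averaged; the target Ct is
#' normalized to the housekeeping gene (dCt = Ct_target - Ct_housekeeping),
#' then to the designated reference sample (ddCt = dCt_sample - dCt_reference);
#' the fold change is 2^-ddCt.  The reference sample has fold change 1 by
#' construction.
#'
#' @param plate a `qpcr_plate`: data.frame with columns `sample_id`, `target`,
#'   `role` (`"target"` or `"housekeeping"`) and replicate columns
#'   `rep1`, `rep2`, ..., plus attribute `reference_sample_id`.
#' @param reference_sample_id reference sample; default taken from the plate
#'   attribute.
#' @return data.frame with `sample_id`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(plate,
                             reference_sample_id = attr(plate, "reference_sample_id")) {
  req <- c("sample_id", "target", "role")
  missing <- setdiff(req, names(plate))
  if (length(missing) > 0)
    format_error(sprintf("qPCR plate missing column(s): %s",
                         paste(missing, collapse = ", ")))
  rep_cols <- grep("^rep[0-9]+$", names(plate), value = TRUE)
  if (length(rep_cols) < 1) format_error("qPCR plate has no replicate columns")
  if (is.null(reference_sample_id) || !nzchar(reference_sample_id))
    format_error("no reference sample designated")
  plate$mean_ct <- rowMeans(plate[, rep_cols, drop = FALSE])
  samples <- unique(plate$sample_id)
  if (!reference_sample_id %in% samples)
    format_error(sprintf("reference sample '%s' not on plate", reference_sample_id))
  dct <- vapply(samples, function(s) {
    tgt <- plate$mean_ct[plate$sample_id == s & plate$role == "target"]
    hk <- plate$mean_ct[plate$sample_id == s & plate$role == "housekeeping"]
    if (length(hk) < 1)
      format_error(sprintf("sample '%s' has no housekeeping measurement", s))
    if (length(tgt) < 1)
      format_error(sprintf("sample '%s' has no target measurement", s))
    mean(tgt) - mean(hk)
  }, numeric(1))
  ddct <- dct - dct[[reference_sample_id]]
  data.frame(sample_id = samples, dct = unname(dct), ddct = unname(ddct),
             fold_change = 2^(-unname(ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}
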