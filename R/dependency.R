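# Control-anchored normalization and threshold calling of gene-effect
# (dependency) scores from CRISPR knockout or RNAi knockdown screens.

#' Two-point control-anchored normalization of gene-effect scores
#'
#' Rescales the raw gene effects of one cell line so that the median of the
#' non-essential control genes maps to 0 and the median of the essential
#' control genes maps to -1, the convention under which a score of about -1
#' means "as deleterious as knocking out a core-essential gene" and 0 means
#' "no growth effect".  The map is the affine function
#' `f(x) = (x - m_ne) / (m_ne - m_e)` with `m_ne`, `m_e` the control medians.
#'
#' @param raw named numeric vector of raw gene effects for one cell line.
#' @param essential_ids,noness_ids character vectors of control gene ids;
#'   both must be present in `names(raw)` and non-empty.
#' @return numeric vector of normalized effects, same names and order as
#'   `raw`.
#' @export
normalize_gene_effects <- function(raw, essential_ids, noness_ids) {
  if (length(essential_ids) < 1 || length(noness_ids) < 1)
    config_error("both control sets must contain at least one gene")
  missing <- setdiff(c(essential_ids, noness_ids), names(raw))
  if (length(missing) > 0)
    feature_error(sprintf("control gene(s) absent from raw effects: %s",
                          paste(utils::head(missing, 5), collapse = ", ")))
  m_e <- stats::median(raw[essential_ids])
  m_ne <- stats::median(raw[noness_ids])
  if (m_ne == m_e)
    degenerate_error("control medians coincide; normalization degenerate")
  (raw - m_ne) / (m_ne - m_e)
}

#' Normalize a long-format dependency panel per cell line
#'
#' Applies [normalize_gene_effects()] within each cell line of a panel with
#' columns `cell_line`, `gene`, `raw_effect`, `control_label` (values
#' `essential`, `non_essential`, `query`).
#'
#' @param panel data.frame in the long format above.
#' @return the panel with a `normalized_effect` column added.
#' @export
normalize_dependency_panel <- function(panel) {
  req <- c("cell_line", "gene", "raw_effect", "control_label")
  missing <- setdiff(req, names(panel))
  if (length(missing) > 0)
    format_error(sprintf("dependency panel missing column(s): %s",
                         paste(missing, collapse = ", ")))
  bad <- setdiff(unique(panel$control_label),
                 c("essential", "non_essential", "query"))
  if (length(bad) > 0)
    format_error(sprintf("unknown control_label value(s): %s",
                         paste(bad, collapse = ", ")))
  panel$normalized_effect <- NA_real_
  for (cl in unique(panel$cell_line)) {
    idx <- panel$cell_line == cl
    raw <- stats::setNames(panel$raw_effect[idx], panel$gene[idx])
    ess <- panel$gene[idx][panel$control_label[idx] == "essential"]
    ne <- panel$gene[idx][panel$control_label[idx] == "non_essential"]
    panel$normalized_effect[idx] <-
      unname(normalize_gene_effects(raw, ess, ne))
  }
  panel
}

#' Call gene dependency from normalized effects
#'
#' A cell line is called dependent on the gene when its normalized gene
#' effect is at or below the threshold (default -0.5, i.e. at least half as
#' deleterious as a typical essential-gene knockout).  The summary verdict is
#' "no significant effect" when no cell line is called dependent.
#'
#' @param normalized named numeric vector of normalized gene effects, one per
#'   cell line.
#' @param threshold dependency threshold, default `-0.5`.
#' @return list with `call` (per-cell-line `dependent`/`not_dependent`),
#'   `fraction_dependent`, and `verdict`.
#' @export
call_dependency <- function(normalized, threshold = -0.5) {
  if (length(normalized) == 0)
    insufficient_error("no normalized scores supplied")
  call <- ifelse(normalized <= threshold, "dependent", "not_dependent")
  frac <- mean(call == "dependent")
  list(call = call,
       fraction_dependent = frac,
       verdict = if (frac == 0) "no significant effect" else
         sprintf("dependent in %.1f%% of cell lines", 100 * frac))
}
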