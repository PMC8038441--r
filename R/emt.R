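# Rank-quadrant EMT classification from a 14-marker panel, median splits,
# and phenotype-level association/comparison analyses.

#' EMT marker panel
#'
#' The default panel is 3 mesenchymal markers (ZEB1, VIM, FN1) and 11
#' epithelial markers (CDH1, EPCAM, ESRP1, ESRP2, DDR1, CTNNB1, CD24, CLDN7,
#' KRT8, KRT19, RAB25).
#'
#' @param mesenchymal,epithelial character vectors of feature ids; both
#'   non-empty and disjoint.
#' @return a `marker_panel` list.
#' @export
marker_panel <- function(mesenchymal = c("ZEB1", "VIM", "FN1"),
                         epithelial = c("CDH1", "EPCAM", "ESRP1", "ESRP2",
                                        "DDR1", "CTNNB1", "CD24", "CLDN7",
                                        "KRT8", "KRT19", "RAB25")) {
  if (length(mesenchymal) < 1 || length(epithelial) < 1)
    config_error("marker panel lists must be non-empty")
  if (length(intersect(mesenchymal, epithelial)) > 0)
    config_error("mesenchymal and epithelial marker lists must be disjoint")
  structure(list(mesenchymal = mesenchymal, epithelial = epithelial),
            class = "marker_panel")
}

#' Aggregate marker score
#'
#' Per-sample mean of log2(TPM + 1) over a marker set.  The log transform
#' keeps one high-abundance marker from dominating the average.
#'
#' @param expr ExpressionMatrix (samples x features, TPM).
#' @param markers character vector of marker feature ids (>= 1), all present
#'   in `expr`.
#' @return named numeric vector of scores, one per sample.
#' @export
aggregate_marker_score <- function(expr, markers) {
  validate_expression_matrix(expr)
  if (length(markers) < 1) config_error("at least one marker required")
  rowMeans(log2p1(get_features(expr, markers)))
}

# Strictly-greater-than-median split; the single tie rule used everywhere.
above_median <- function(x) x > stats::median(x)

phenotype_levels <- c("Epithelial", "Mesenchymal", "HighOverlap", "LowOverlap")

quadrant_label <- function(mes_top, epi_top) {
  factor(ifelse(mes_top & epi_top, "HighOverlap",
         ifelse(mes_top & !epi_top, "Mesenchymal",
         ifelse(!mes_top & epi_top, "Epithelial", "LowOverlap"))),
         levels = phenotype_levels)
}

#' Classify samples into four EMT quadrant phenotypes
#'
#' Computes an aggregate mesenchymal and an aggregate epithelial score per
#' sample and splits the cohort at the median of each score: samples strictly
#' above both medians are `HighOverlap`, above mesenchymal only are
#' `Mesenchymal`, above epithelial only are `Epithelial`, and at-or-below
#' both are `LowOverlap`.  Being rank-based, the classification is invariant
#' to any strictly increasing transform of the scores.
#'
#' @param expr ExpressionMatrix with >= 4 samples containing all panel
#'   markers.
#' @param panel a [marker_panel()].
#' @param score_mode `"mean"` (default): per-sample mean of log2(TPM+1) over
#'   markers, then rank against the cohort; `"rank_mean"`: rank each marker
#'   across samples first, then average the per-marker ranks.
#' @return data.frame (class `emt_calls`) in input sample order with columns
#'   `sample_id`, `mes_score`, `epi_score`, `mes_top`, `epi_top`,
#'   `phenotype`.
#' @export
classify_emt_quadrants <- function(expr, panel = marker_panel(),
                                   score_mode = c("mean", "rank_mean")) {
  score_mode <- match.arg(score_mode)
  validate_expression_matrix(expr)
  if (nrow(expr) < 4)
    insufficient_error("classification requires at least 4 samples")
  if (!inherits(panel, "marker_panel"))
    panel <- do.call(marker_panel, panel)
  score <- function(markers) {
    if (score_mode == "mean") {
      aggregate_marker_score(expr, markers)
    } else {
      rowMeans(apply(log2p1(get_features(expr, markers)), 2, rank))
    }
  }
  mes <- score(panel$mesenchymal)
  epi <- score(panel$epithelial)
  mes_top <- above_median(mes)
  epi_top <- above_median(epi)
  structure(
    data.frame(sample_id = rownames(expr), mes_score = unname(mes),
               epi_score = unname(epi), mes_top = unname(mes_top),
               epi_top = unname(epi_top),
               phenotype = quadrant_label(unname(mes_top), unname(epi_top)),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("emt_calls", "data.frame"))
}

#' Median split on one gene
#'
#' Labels each sample `top` when its expression is strictly greater than the
#' cohort median of that gene, `bottom` otherwise — the same tie rule as the
#' quadrant classifier.  Used e.g. to split cell-line panels by ZEB1 into a
#' more-mesenchymal (top) and more-epithelial (bottom) half.
#'
#' @param expr ExpressionMatrix with >= 2 samples.
#' @param feature_id the gene to split on.
#' @return named character vector (`top`/`bottom`) per sample.
#' @export
split_by_median_gene <- function(expr, feature_id) {
  validate_expression_matrix(expr)
  if (nrow(expr) < 2) insufficient_error("median split requires >= 2 samples")
  v <- get_features(expr, feature_id)[, 1]
  stats::setNames(ifelse(above_median(v), "top", "bottom"), rownames(expr))
}

#' Chi-square association between EMT phenotype and a categorical label
#'
#' Builds the phenotype x label contingency table (empty phenotype rows
#' dropped) and applies the Pearson chi-square test without continuity
#' correction.
#'
#' @param calls `emt_calls` from [classify_emt_quadrants()].
#' @param labels per-sample categorical labels, aligned to `calls` (same
#'   order, or named by sample id).
#' @return an `emtquad_test` with the contingency table as field `table`.
#' @export
phenotype_association_test <- function(calls, labels) {
  if (!is.null(names(labels))) labels <- labels[calls$sample_id]
  if (length(labels) != nrow(calls))
    format_error("labels not aligned to EMT calls")
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    degenerate_error("labels must have at least 2 levels")
  tab <- table(phenotype = calls$phenotype, label = labels)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  out <- chi_square(tab)
  out$table <- tab
  out
}

#' Compare a per-sample quantity across EMT phenotypes
#'
#' One-way ANOVA over the four phenotype groups plus all pairwise Tukey HSD
#' comparisons.  Used e.g. for isoform expression or stromal scores across
#' phenotypes.  Phenotypes with fewer than 2 samples are dropped with a
#' warning.
#'
#' @param values per-sample numeric vector aligned to `calls` (same order, or
#'   named by sample id).
#' @param calls `emt_calls`.
#' @return list with `anova` (an `emtquad_test`) and `tukey` (pairwise
#'   data.frame).
#' @export
compare_across_phenotypes <- function(values, calls) {
  if (!is.null(names(values))) values <- values[calls$sample_id]
  if (length(values) != nrow(calls))
    format_error("values not aligned to EMT calls")
  g <- droplevels(calls$phenotype)
  list(anova = anova_oneway(values, g),
       tukey = suppressWarnings(tukey_hsd(values, g)))
}
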