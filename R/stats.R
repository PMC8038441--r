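# Shared statistical kernel.  Every hypothesis test used by the higher-level
# modules funnels through these wrappers so that conventions (two-sided p,
# pooled-variance default, no continuity correction) are set in one place.

test_result <- function(statistic, df, p, estimate = NA_real_,
                        ci = c(NA_real_, NA_real_), method = "") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), estimate = unname(estimate),
                 ci = unname(ci), method = method),
            class = "emtquad_test")
}

#' @export
print.emtquad_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ","),
              x$p))
  if (!all(is.na(x$estimate)))
    cat(sprintf("  estimate = %.4g\n", x$estimate))
  invisible(x)
}

#' Two-sample t-test
#'
#' Two-sided Student's t-test, pooled variance by default (`pooled = FALSE`
#' gives Welch).  Two identical constant samples are reported as
#' statistic 0, p = 1 rather than an error.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled logical; pooled-variance (classical Student) if `TRUE`.
#' @return an `emtquad_test` with the mean difference as estimate.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    insufficient_error("two_sample_t requires n >= 2 in each sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_result(0, length(x) + length(y) - 2, 1,
                         estimate = 0, method = "two-sample t (degenerate)"))
    }
    degenerate_error("both samples constant with unequal means: t undefined")
  }
  fit <- stats::t.test(x, y, var.equal = pooled)
  test_result(fit$statistic, fit$parameter, fit$p.value,
              estimate = mean(x) - mean(y),
              ci = unname(fit$conf.int),
              method = if (pooled) "two-sample t (pooled)" else "Welch t")
}

#' Pearson correlation with t-approximation p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return an `emtquad_test` with r as the estimate.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) degenerate_error("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) insufficient_error("pearson_cor requires n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    degenerate_error("correlation undefined for constant input")
  fit <- stats::cor.test(x, y, method = "pearson")
  test_result(fit$statistic, fit$parameter, fit$p.value,
              estimate = unname(fit$estimate), ci = unname(fit$conf.int),
              method = "Pearson correlation")
}

#' Partial correlation of x and y controlling for z
#'
#' First-order partial correlation
#' r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)),
#' with a two-sided p-value from t = r sqrt((n-3)/(1-r^2)) on n - 3 df.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return an `emtquad_test` with the partial r as the estimate.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) degenerate_error("input lengths differ")
  if (n < 4) insufficient_error("partial_correlation requires n >= 4")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0)
    degenerate_error("partial correlation undefined for constant input")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    degenerate_error("a control correlation is +/-1; partial correlation degenerate")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  df <- n - 3
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  test_result(tval, df, p, estimate = r, method = "partial correlation")
}

# Drop groups with fewer than 2 observations, warning; error if < 2 remain.
drop_small_groups <- function(values, groups, min_n = 2) {
  groups <- factor(groups)
  tab <- table(groups)
  small <- names(tab)[tab < min_n]
  if (length(small) > 0) {
    warning(sprintf("dropping group(s) with < %d observations: %s",
                    min_n, paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2)
    insufficient_error("fewer than 2 usable groups")
  list(values = values, groups = groups)
}

#' One-way ANOVA
#'
#' @param values numeric vector.
#' @param groups group labels aligned to `values`; groups with fewer than
#'   2 observations are dropped with a warning.
#' @return an `emtquad_test`; `df` is `c(k - 1, N - k)`.
#' @export
anova_oneway <- function(values, groups) {
  d <- drop_small_groups(values, groups)
  fit <- stats::aov(d$values ~ d$groups)
  tab <- summary(fit)[[1]]
  test_result(tab[1, "F value"], c(tab[1, "Df"], tab[2, "Df"]),
              tab[1, "Pr(>F)"], method = "one-way ANOVA")
}

#' Tukey honestly-significant-difference post-hoc test
#'
#' Pairwise comparisons after a one-way ANOVA, adjusted via the studentized
#' range distribution.
#'
#' @inheritParams anova_oneway
#' @return data.frame with one row per pair: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  d <- drop_small_groups(values, groups)
  dat <- data.frame(v = d$values, g = d$groups)
  fit <- stats::aov(v ~ g, data = dat)
  tk <- stats::TukeyHSD(fit)[[1]]
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction.  Reports expected counts and flags tables with
#' any expected cell count below 5, where the asymptotic p is unreliable.
#'
#' @param tab 2-D contingency table (matrix of non-negative counts) with all
#'   row and column margins positive.
#' @return an `emtquad_test` with extra fields `expected` and `low_expected`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (length(dim(tab)) != 2 || any(tab < 0))
    format_error("chi_square requires a 2-D table of non-negative counts")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    degenerate_error("chi_square requires at least 2 rows and 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    degenerate_error("chi_square table has a zero margin")
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- test_result(fit$statistic, fit$parameter, fit$p.value,
                     method = "Pearson chi-square")
  out$expected <- fit$expected
  out$low_expected <- any(fit$expected < 5)
  out
}
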