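# Cutoff-based prognostic stratification: Kaplan-Meier estimation, log-rank
# tests and univariate hazard ratios, overall and within EMT phenotypes.
# The heavy lifting is delegated to the survival package (product-limit
# estimator, k-group log-rank, Cox partial likelihood with Breslow ties).

#' Dichotomize samples at an expression cutoff
#'
#' `high` when the value is greater than or equal to the cutoff, `low`
#' otherwise (a value exactly at the cutoff is high).  With the default TPM
#' cutoff of 1.5 this reproduces a top-expressors-versus-the-rest split.
#'
#' @param values finite numeric vector.
#' @param cutoff numeric scalar.
#' @return character vector of `high`/`low` labels (names preserved) with the
#'   realized high fraction attached as attribute `high_fraction`.
#' @export
stratify_by_cutoff <- function(values, cutoff) {
  if (any(!is.finite(values)))
    format_error("stratify_by_cutoff requires finite values")
  out <- ifelse(values >= cutoff, "high", "low")
  names(out) <- names(values)
  attr(out, "high_fraction") <- mean(out == "high")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator for one group.  Censored
#' observations reduce the at-risk count but never drop the curve.
#'
#' @param times positive event/censoring times.
#' @param events binary event indicator (1 = event, 0 = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv, row.names = NULL)
}

check_surv_input <- function(times, events, groups = NULL) {
  if (length(times) == 0) insufficient_error("empty survival input")
  if (length(events) != length(times))
    format_error("times and events lengths differ")
  if (any(!is.finite(times)) || any(times <= 0))
    format_error("survival times must be finite and > 0")
  if (!all(events %in% c(0, 1)))
    format_error("event indicator must be binary 0/1")
  if (!is.null(groups) && length(groups) != length(times))
    format_error("groups not aligned to times")
  invisible(NULL)
}

#' Log-rank test across k groups
#'
#' Standard (unweighted) log-rank chi-square comparing the survival
#' distributions of two or more groups; df = k - 1.
#'
#' @param times positive times.
#' @param events binary event indicator.
#' @param groups group labels, >= 2 distinct values.
#' @return an `emtquad_test`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events, groups)
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    insufficient_error("log-rank test requires >= 2 groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1
  test_result(fit$chisq, df, stats::pchisq(fit$chisq, df, lower.tail = FALSE),
              method = "log-rank")
}

#' Univariate hazard ratio with Wald 95% CI
#'
#' Proportional-hazards estimate for a binary group indicator: Cox partial
#' likelihood with Breslow tie handling, Newton-Raphson to convergence
#' tolerance 1e-9; the Wald 95% interval is formed on the log scale and
#' exponentiated.  The HR is for the non-reference level relative to the
#' reference; by default the reference is the first factor level of
#' `binary_group` (pass `reference` to control it, e.g. `reference = "low"`
#' for a high-vs-low comparison).
#'
#' @param times positive times.
#' @param events binary event indicator; at least one event required.
#' @param binary_group two-level group labels, both levels non-empty.
#' @param reference optional reference level (the denominator of the HR).
#' @return list with `hr`, `ci_lo`, `ci_hi`, `log_hr`, `se`, `p`, `n`,
#'   `n_events`, `reference`.
#' @export
hazard_ratio <- function(times, events, binary_group, reference = NULL) {
  check_surv_input(times, events, binary_group)
  g <- factor(binary_group)
  if (nlevels(droplevels(g)) != 2)
    insufficient_error("hazard_ratio requires exactly 2 non-empty groups")
  if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
  if (sum(events) < 1)
    nonestimable_error("no events observed; hazard ratio non-estimable")
  # near-separation makes coxph warn about infinite coefficients; that case
  # is detected explicitly below, so the warning is muffled here
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph(survival::Surv(times, events) ~ g, ties = "breslow",
                      control = survival::coxph.control(eps = 1e-9,
                                                        iter.max = 100))),
    error = function(e) nonestimable_error(paste("Cox fit failed:",
                                                 conditionMessage(e))))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    nonestimable_error("complete separation: hazard ratio non-estimable")
  list(hr = exp(beta),
       ci_lo = exp(beta - stats::qnorm(0.975) * se),
       ci_hi = exp(beta + stats::qnorm(0.975) * se),
       log_hr = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       n = length(times), n_events = sum(events),
       reference = levels(g)[1])
}

#' Cutoff survival analysis within each EMT phenotype
#'
#' For each of the four quadrant phenotypes, stratifies the samples of that
#' phenotype at the expression cutoff of one feature and reports the
#' two-group log-rank test and hazard ratio (high vs low).  Phenotypes where
#' either stratum is empty, or with too few events, are reported as
#' non-estimable rather than dropped.
#'
#' @param expr ExpressionMatrix.
#' @param clinical ClinicalTable (validated).
#' @param calls `emt_calls` for the same samples.
#' @param feature_id feature to stratify on (TPM scale).
#' @param cutoff TPM cutoff, default 1.5.
#' @return data.frame with exactly one row per phenotype: group sizes,
#'   log-rank statistic/p, HR with CI, and an `estimable` flag.
#' @export
per_phenotype_survival <- function(expr, clinical, calls, feature_id,
                                   cutoff = 1.5) {
  validate_expression_matrix(expr)
  validate_clinical_table(clinical)
  ids <- Reduce(intersect, list(rownames(expr), clinical$sample_id,
                                calls$sample_id))
  if (length(ids) < 4)
    insufficient_error("fewer than 4 samples shared across inputs")
  expr <- expr[ids, , drop = FALSE]
  clin <- clinical[match(ids, clinical$sample_id), ]
  pheno <- calls$phenotype[match(ids, calls$sample_id)]
  strat <- stratify_by_cutoff(get_features(expr, feature_id)[, 1], cutoff)
  out <- data.frame(phenotype = phenotype_levels, n = 0L, n_high = 0L,
                    n_low = 0L, n_events = 0L, logrank_stat = NA_real_,
                    logrank_p = NA_real_, hr = NA_real_, hr_lo = NA_real_,
                    hr_hi = NA_real_, estimable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(phenotype_levels)) {
    idx <- pheno == phenotype_levels[i]
    out$n[i] <- sum(idx)
    out$n_high[i] <- sum(strat[idx] == "high")
    out$n_low[i] <- sum(strat[idx] == "low")
    out$n_events[i] <- sum(clin$event[idx])
    if (out$n_high[i] == 0 || out$n_low[i] == 0 || out$n_events[i] == 0)
      next
    lr <- logrank_test(clin$time[idx], clin$event[idx], strat[idx])
    out$logrank_stat[i] <- lr$statistic
    out$logrank_p[i] <- lr$p
    hr <- tryCatch(
      hazard_ratio(clin$time[idx], clin$event[idx], strat[idx],
                   reference = "low"),
      emtquad_nonestimable_error = function(e) NULL)
    if (is.null(hr)) next
    out$hr[i] <- hr$hr
    out$hr_lo[i] <- hr$ci_lo
    out$hr_hi[i] <- hr$ci_hi
    out$estimable[i] <- TRUE
  }
  out
}
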