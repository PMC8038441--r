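# Independent oracles used to cross-check the implementation.  Each is
# deliberately written by a different route than the package code path.

# Brute-force quadrant oracle: sort-based median, explicit per-sample mapping.
oracle_quadrants <- function(mes, epi) {
  med_of <- function(s) {
    s <- sort(s)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  m_med <- med_of(mes)
  e_med <- med_of(epi)
  out <- character(length(mes))
  for (i in seq_along(mes)) {
    m_top <- mes[i] > m_med
    e_top <- epi[i] > e_med
    out[i] <- if (m_top && e_top) "HighOverlap"
      else if (m_top) "Mesenchymal"
      else if (e_top) "Epithelial"
      else "LowOverlap"
  }
  out
}

# Pearson chi-square statistic from first principles (no stats::chisq.test).
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Monte-Carlo permutation p-value for independence in a two-way table built
# from per-sample labels.
oracle_perm_p <- function(a, b, n_perm = 2000) {
  obs <- oracle_chisq_stat(table(a, b))
  hits <- 0
  for (k in seq_len(n_perm)) {
    stat <- oracle_chisq_stat(table(a, sample(b)))
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Partial correlation via the residual-regression definition.
oracle_partial_cor <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Cox partial likelihood (Breslow) for a binary covariate, maximized on a
# grid by stats::optimize — an independent route to the HR.
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(times, events, x) {
  stats::optimize(function(b) oracle_cox_loglik(b, times, events, x),
                  interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Small random expression matrix with valid ids.
random_expr <- function(n_samples, features) {
  m <- matrix(stats::rexp(n_samples * length(features), rate = 0.2),
              nrow = n_samples,
              dimnames = list(sprintf("S%03d", seq_len(n_samples)), features))
  m
}
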