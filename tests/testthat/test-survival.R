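test_that("cutoff stratification uses >= and reports the realized fraction", {
  s <- stratify_by_cutoff(c(0.0, 1.49, 1.5, 7.2), 1.5)
  expect_equal(unname(s), c("low", "low", "high", "high"),
               ignore_attr = TRUE)
  expect_equal(attr(s, "high_fraction"), 0.5)

  s0 <- stratify_by_cutoff(c(0.1, 0.2), 1.5)
  expect_true(all(s0 == "low"))
  expect_equal(attr(s0, "high_fraction"), 0)
  expect_error(stratify_by_cutoff(c(1, NA), 1.5),
               class = "emtquad_format_error")
})

test_that("Kaplan-Meier estimate matches hand-computed product-limit tables", {
  # no censoring: equals the empirical survival function
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # all censored: flat at 1
  kmc <- km_estimate(c(2, 4, 9), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))

  # mixed 6-subject fixture: times 1, 2+, 3, 4, 4, 5+
  # S(1) = 5/6; S(3) = 5/6 * 3/4 = 0.625; S(4) = 0.625 * 1/3
  kmm <- km_estimate(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 1, 0))
  expect_equal(kmm$surv[kmm$time == 1], 5 / 6)
  expect_equal(kmm$surv[kmm$time == 3], 5 / 6 * 3 / 4)
  expect_equal(kmm$surv[kmm$time == 4], 5 / 6 * 3 / 4 * 1 / 3)
  expect_equal(kmm$n_risk, c(6, 5, 4, 3, 1))
  # non-increasing, in [0, 1], starts from 1 implicitly
  expect_true(all(diff(kmm$surv) <= 0))
  expect_true(all(kmm$surv >= 0 & kmm$surv <= 1))
  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "emtquad_insufficient_error")
})

test_that("log-rank matches the observed-minus-expected hand oracle", {
  # duplicated groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 4)
  e0 <- c(1, 0, 1, 1)
  r0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  # 6-subject worked example, hand computation:
  # A: 1, 3, 5+; B: 2+, 4, 4.  O_A = 2, E_A = 0.5 + 0.5 + 2/3 = 5/3,
  # V = 1/4 + 1/4 + 2/9 = 13/18, statistic = (1/3)^2 / (13/18) = 2/13
  r <- logrank_test(c(1, 3, 5, 2, 4, 4), c(1, 1, 0, 0, 1, 1),
                    c("A", "A", "A", "B", "B", "B"))
  expect_equal(r$statistic, 2 / 13, tolerance = 1e-10)
  expect_equal(r$df, 1)

  # invariant to strictly increasing time transforms (rank-based)
  tt <- c(1, 3, 5, 2, 4, 4)
  r2 <- logrank_test(exp(tt), c(1, 1, 0, 0, 1, 1),
                     c("A", "A", "A", "B", "B", "B"))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)

  expect_error(logrank_test(t0, e0, rep("a", 4)),
               class = "emtquad_insufficient_error")
})

test_that("four-group log-rank has df 3 and detects separated groups", {
  set.seed(401)
  g <- rep(c("p1", "p2", "p3", "p4"), each = 40)
  rate <- rep(c(0.1, 0.1, 0.1, 0.5), each = 40)
  tm <- rexp(160, rate)
  cn <- runif(160, 0, 15)
  r <- logrank_test(pmin(tm, cn), as.integer(tm <= cn), g)
  expect_equal(r$df, 3)
  expect_lt(r$p, 0.01)
})

test_that("hazard ratio matches the grid-maximized partial likelihood and is symmetric", {
  set.seed(402)
  n <- 60
  x <- rep(c(0, 1), each = n / 2)
  tm <- rexp(n, 0.1 * exp(0.7 * x))
  cn <- runif(n, 0, 25)
  time <- pmin(tm, cn)
  ev <- as.integer(tm <= cn)
  grp <- ifelse(x == 1, "high", "low")

  hr <- hazard_ratio(time, ev, grp, reference = "low")
  beta_oracle <- oracle_cox_beta(time, ev, x)
  expect_equal(hr$log_hr, beta_oracle, tolerance = 1e-6)
  expect_true(hr$ci_lo <= hr$hr && hr$hr <= hr$ci_hi)

  # swapping labels reciprocates the HR and reverses the CI
  hr2 <- hazard_ratio(time, ev, grp, reference = "high")
  expect_equal(hr2$hr, 1 / hr$hr, tolerance = 1e-8)
  expect_equal(hr2$ci_lo, 1 / hr$ci_hi, tolerance = 1e-8)
  expect_equal(hr2$ci_hi, 1 / hr$ci_lo, tolerance = 1e-8)

  # 4-subject, 2-event, no-tie instance against the same oracle
  t4 <- c(1, 2, 3, 4)
  e4 <- c(1, 0, 1, 0)
  g4 <- c("high", "low", "low", "high")
  hr4 <- hazard_ratio(t4, e4, g4, reference = "low")
  expect_equal(hr4$log_hr, oracle_cox_beta(t4, e4, c(1, 0, 0, 1)),
               tolerance = 1e-5)

  # no events at all, and complete separation (all events in one group
  # with that group leaving the risk set), are non-estimable
  expect_error(hazard_ratio(c(1, 2, 3, 4), c(0, 0, 0, 0), g4),
               class = "emtquad_nonestimable_error")
  expect_error(hazard_ratio(t4, e4, c("high", "low", "high", "low"),
                            reference = "low"),
               class = "emtquad_nonestimable_error")
})

test_that("per-phenotype survival reports all four phenotypes and flags non-estimable strata", {
  cfg <- sim_config(seed = 403, n_tumors = 200)
  co <- simulate_cohort(cfg)
  calls <- classify_emt_quadrants(co$expression)
  res <- per_phenotype_survival(co$expression, co$clinical, calls,
                                "ZNF71_KRAB", cutoff = 1.5)
  expect_equal(nrow(res), 4)
  expect_setequal(res$phenotype,
                  c("Epithelial", "Mesenchymal", "HighOverlap", "LowOverlap"))
  expect_equal(res$n_high + res$n_low, res$n)
  expect_equal(sum(res$n), 200)

  # an absurd cutoff empties every high stratum: all rows non-estimable,
  # none dropped
  res2 <- per_phenotype_survival(co$expression, co$clinical, calls,
                                 "ZNF71_KRAB", cutoff = 1e9)
  expect_equal(nrow(res2), 4)
  expect_false(any(res2$estimable))
})
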