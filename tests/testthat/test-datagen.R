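test_that("config validation names the offending field", {
  expect_error(sim_config(n_tumors = 2), "n_tumors",
               class = "emtquad_config_error")
  expect_error(sim_config(iso_corr_rho = 1.2), "iso_corr_rho",
               class = "emtquad_config_error")
  expect_error(sim_config(logsd = 0), "logsd",
               class = "emtquad_config_error")
  expect_error(sim_config(drug_params = list()), "drug_params",
               class = "emtquad_config_error")
  expect_error(sim_config(effect_phenotype = "Weird"), "effect_phenotype",
               class = "emtquad_config_error")
})

test_that("cohort simulation is deterministic with the stated shape", {
  cfg <- sim_config(seed = 1, n_tumors = 197)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a$expression), 197)
  expect_equal(nrow(a$clinical), 197)
  expect_identical(rownames(a$expression), a$clinical$sample_id)
  expect_true(all(c("ZNF71_overall", "ZNF71_KRAB", "ZNF71_KRABless",
                    "ZEB1", "VIM", "FN1", "CDH1") %in%
                    colnames(a$expression)))
  expect_true(all(a$expression >= 0))
  expect_true(all(a$clinical$time > 0))
  expect_true(all(a$clinical$event %in% c(0, 1)))
  # truth sidecar aligned and containing the planted labels
  expect_identical(a$truth$sample_id, a$clinical$sample_id)
  expect_true(all(a$truth$phenotype %in%
                    c("Epithelial", "Mesenchymal", "HighOverlap", "LowOverlap")))
})

test_that("generator recovers the planted isoform correlation and high fraction", {
  co <- simulate_cohort(sim_config(seed = 1, n_tumors = 5000,
                                   iso_corr_rho = 0.6))
  lk <- log2(co$expression[, "ZNF71_KRAB"] + 1)
  lkl <- log2(co$expression[, "ZNF71_KRABless"] + 1)
  r <- pearson_cor(lk, lkl)$estimate
  expect_lt(abs(r - 0.6), 0.03)

  # planted exceedance probability of the TPM cutoff
  frac <- mean(co$expression[, "ZNF71_KRAB"] >= 1.5)
  expect_lt(abs(frac - 0.17), 3 * sqrt(0.17 * 0.83 / 5000) + 0.01)

  # ~60% events under the default hazard/censoring settings
  expect_gt(mean(co$clinical$event), 0.55)
  expect_lt(mean(co$clinical$event), 0.72)
})

test_that("cell-line simulation is deterministic, sized, and null-calibrated", {
  cfg <- sim_config(seed = 5, n_cell_lines = 117)
  a <- simulate_cell_lines(cfg)
  b <- simulate_cell_lines(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$expression), 117)
  expect_equal(length(unique(a$drug_response$cell_line)), 117)
  expect_equal(length(unique(a$dependency$cell_line)), 117)
  expect_setequal(unique(a$drug_response$drug),
                  c("carboplatin", "cisplatin", "paclitaxel", "docetaxel",
                    "gemcitabine", "vinorelbine", "etoposide", "gefitinib",
                    "erlotinib"))

  # with no planted shift anywhere, hidden resistant vs sensitive labels are
  # unrelated to expression: ~5% of per-gene t-tests significant at 0.05
  null_dp <- default_drug_params_null <- list(
    drugA = list(ic50_logmean = 0, ic50_logsd = 1, ec50_logmean = 0,
                 ec50_logsd = 1, shift_genes = character(0), shift = 0))
  cfg0 <- sim_config(seed = 6, n_cell_lines = 100,
                     n_background_genes = 1000, drug_params = null_dp)
  sim0 <- simulate_cell_lines(cfg0)
  lab <- setNames(sim0$truth$hidden_label, sim0$truth$cell_line)
  bg <- grep("^BG", colnames(sim0$expression), value = TRUE)
  de <- diff_expr_by_response(sim0$expression, lab, features = bg)
  rej <- mean(de$p < 0.05)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("planted drug expression shifts land in hidden-resistant lines", {
  cfg <- sim_config(seed = 7, n_cell_lines = 117)
  sim <- simulate_cell_lines(cfg)
  tr <- sim$truth[sim$truth$drug == "docetaxel", ]
  lab <- setNames(tr$hidden_label, tr$cell_line)
  de <- diff_expr_by_response(sim$expression, lab,
                              features = c("ZNF71_KRAB", "ZNF71_overall"))
  expect_true(all(de$diff > 0))
  expect_true(all(de$p < 0.05))
})

test_that("qPCR plate honors planted ddCt, technical SD and determinism", {
  cfg <- sim_config(seed = 8,
                    qpcr_params = list(n_samples = 2, target = "ZNF71_KRAB",
                                       housekeeping = "UBC", base_ct = 27,
                                       hk_ct = 20, tech_sd = 0,
                                       ddct = c(0, -2)))
  plate <- simulate_qpcr(cfg)
  expect_identical(plate, simulate_qpcr(cfg))
  # zero technical SD: replicates identical
  expect_true(all(plate$rep1 == plate$rep2 & plate$rep2 == plate$rep3))
  fc <- ddct_fold_change(plate)
  # planted ddCt -2 chains to fold change 2^2 = 4 exactly
  expect_equal(fc$fold_change[fc$sample_id == "S01"], 1)
  expect_equal(fc$fold_change[fc$sample_id == "S02"], 4)
})
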