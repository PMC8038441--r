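# Synthetic tumor cohorts, cell-line panels and qPCR plates with the
# statistical structure the downstream analyses assume.  Expression follows
# TPM = 2^x - 1 truncated at 0 with x Gaussian (baseline + loading * latent
# axis + noise), so that log2(TPM + 1) analyses downstream see (truncated)
# Gaussian data.  Ground-truth labels are returned in a separate `truth`
# element that no analysis operation reads.

default_drug_params <- function() {
  base <- list(ic50_logmean = 0, ic50_logsd = 1,
               ec50_logmean = -0.5, ec50_logsd = 1,
               shift_genes = character(0), shift = 0)
  drugs <- c("carboplatin", "cisplatin", "paclitaxel", "docetaxel",
             "gemcitabine", "vinorelbine", "etoposide", "gefitinib",
             "erlotinib")
  out <- stats::setNames(rep(list(base), length(drugs)), drugs)
  # planted expression shifts mirroring the associations the pipeline is
  # meant to detect: KRAB isoform up in docetaxel/paclitaxel-resistant lines,
  # KRAB-less down in gemcitabine-resistant lines
  out$docetaxel$shift_genes <- "ZNF71_KRAB"
  out$docetaxel$shift <- 1
  out$paclitaxel$shift_genes <- "ZNF71_KRAB"
  out$paclitaxel$shift <- 1
  out$gemcitabine$shift_genes <- "ZNF71_KRABless"
  out$gemcitabine$shift <- -0.8
  out
}

default_dep_params <- function() {
  list(n_essential = 50L, n_nonessential = 200L,
       essential_mean = -1.2, essential_sd = 0.2,
       noness_mean = 0.05, noness_sd = 0.15,
       query_genes = "ZNF71", query_mean = 0, query_sd = 0.15)
}

default_qpcr_params <- function() {
  list(n_samples = 6L, target = "ZNF71_KRAB", housekeeping = "UBC",
       base_ct = 25, hk_ct = 20, tech_sd = 0.15, ddct = NULL)
}

#' Simulation configuration
#'
#' Validated parameter set for all three generators.  Scales are log2 TPM
#' unless noted.  The KRAB isoform location defaults to the calibration
#' `log2(tpm_cutoff + 1) - qnorm(1 - high_fraction) * logsd`, which makes the
#' probability of exceeding the TPM cutoff equal to `high_fraction` without
#' distorting the isoform correlation.
#'
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @param n_tumors,n_cell_lines cohort sizes (>= 4); defaults 197 and 117.
#' @param iso_corr_rho correlation between log KRAB and log KRAB-less
#'   expression, in `[-1, 1]`.
#' @param krab_logmean,krabless_logmean,logsd log2-scale location/scale of
#'   the isoform expression; `krab_logmean = NULL` applies the cutoff
#'   calibration above.
#' @param emt_axis_corr correlation between the latent epithelial and
#'   mesenchymal axes.
#' @param marker_loading per-marker effect of its latent axis (log2 units per
#'   axis SD).
#' @param marker_baseline log2-scale marker baseline expression.
#' @param noise_sd residual log2-expression SD.
#' @param true_log_hr planted log hazard ratio for the high-expression group;
#'   default `log(1.686)`.
#' @param baseline_hazard exponential event rate per time unit for the
#'   low-expression group; with `censor_max` the defaults give ~62% events.
#' @param censor_max upper bound of uniform administrative censoring (time
#'   units).
#' @param high_fraction expected fraction of samples above the TPM cutoff.
#' @param tpm_cutoff the TPM cutoff the cohort is calibrated around (1.5).
#' @param effect_phenotype optional quadrant name; when set, the planted
#'   hazard effect applies only to high-expression samples whose *latent*
#'   phenotype matches (used for per-phenotype power experiments).
#' @param n_background_genes number of null background genes in cell-line
#'   expression matrices.
#' @param drug_params named list, one entry per drug, each with
#'   `ic50_logmean`, `ic50_logsd`, `ec50_logmean`, `ec50_logsd`,
#'   `shift_genes`, `shift` (log2 shift added to hidden-resistant lines).
#' @param dep_params list of control-set sizes and normal parameters for
#'   essential/non-essential/query gene effects.
#' @param qpcr_params list: `n_samples`, `target`, `housekeeping`, `base_ct`,
#'   `hk_ct`, `tech_sd`, and optional planted `ddct` vector (first sample is
#'   the reference and must be 0).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_tumors = 197L,
                       n_cell_lines = 117L,
                       iso_corr_rho = 0.6,
                       krab_logmean = NULL,
                       krabless_logmean = 0.6,
                       logsd = 0.5,
                       emt_axis_corr = -0.3,
                       marker_loading = 2,
                       marker_baseline = 4,
                       noise_sd = 0.5,
                       true_log_hr = log(1.686),
                       baseline_hazard = 0.04,
                       censor_max = 60,
                       high_fraction = 0.17,
                       tpm_cutoff = 1.5,
                       effect_phenotype = NULL,
                       n_background_genes = 50L,
                       drug_params = default_drug_params(),
                       dep_params = default_dep_params(),
                       qpcr_params = default_qpcr_params()) {
  chk_num <- function(x, field, lo = -Inf, hi = Inf, gt = NULL) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        x < lo || x > hi || (!is.null(gt) && x <= gt))
      config_error(sprintf("invalid config field '%s'", field))
  }
  chk_num(seed, "seed")
  chk_num(n_tumors, "n_tumors", lo = 4)
  chk_num(n_cell_lines, "n_cell_lines", lo = 4)
  chk_num(iso_corr_rho, "iso_corr_rho", lo = -1, hi = 1)
  chk_num(emt_axis_corr, "emt_axis_corr", lo = -1, hi = 1)
  chk_num(logsd, "logsd", gt = 0)
  chk_num(noise_sd, "noise_sd", lo = 0)
  chk_num(marker_loading, "marker_loading")
  chk_num(marker_baseline, "marker_baseline")
  chk_num(true_log_hr, "true_log_hr")
  chk_num(baseline_hazard, "baseline_hazard", gt = 0)
  chk_num(censor_max, "censor_max", gt = 0)
  chk_num(high_fraction, "high_fraction", lo = 0, hi = 1)
  chk_num(tpm_cutoff, "tpm_cutoff", lo = 0)
  chk_num(n_background_genes, "n_background_genes", lo = 0)
  chk_num(krabless_logmean, "krabless_logmean")
  if (is.null(krab_logmean)) {
    krab_logmean <- log2(tpm_cutoff + 1) -
      stats::qnorm(1 - high_fraction) * logsd
  } else {
    chk_num(krab_logmean, "krab_logmean")
  }
  if (!is.null(effect_phenotype) &&
      !effect_phenotype %in% phenotype_levels)
    config_error("invalid config field 'effect_phenotype'")
  if (!is.list(drug_params) || length(drug_params) < 1 ||
      is.null(names(drug_params)))
    config_error("invalid config field 'drug_params' (need >= 1 named drug)")
  for (d in names(drug_params)) {
    p <- drug_params[[d]]
    for (f in c("ic50_logmean", "ic50_logsd", "ec50_logmean", "ec50_logsd"))
      if (is.null(p[[f]]) || !is.finite(p[[f]]))
        config_error(sprintf("invalid config field 'drug_params.%s.%s'", d, f))
    if (p$ic50_logsd <= 0 || p$ec50_logsd <= 0)
      config_error(sprintf("invalid config field 'drug_params.%s' (SD <= 0)", d))
  }
  dp <- dep_params
  if (dp$n_essential < 1 || dp$n_nonessential < 1 ||
      dp$essential_sd <= 0 || dp$noness_sd <= 0 || dp$query_sd <= 0)
    config_error("invalid config field 'dep_params'")
  qp <- qpcr_params
  if (qp$n_samples < 2 || qp$tech_sd < 0)
    config_error("invalid config field 'qpcr_params'")
  if (!is.null(qp$ddct) && length(qp$ddct) != qp$n_samples)
    config_error("invalid config field 'qpcr_params.ddct' (length mismatch)")
  structure(list(seed = as.integer(seed), n_tumors = as.integer(n_tumors),
                 n_cell_lines = as.integer(n_cell_lines),
                 iso_corr_rho = iso_corr_rho, krab_logmean = krab_logmean,
                 krabless_logmean = krabless_logmean, logsd = logsd,
                 emt_axis_corr = emt_axis_corr,
                 marker_loading = marker_loading,
                 marker_baseline = marker_baseline, noise_sd = noise_sd,
                 true_log_hr = true_log_hr,
                 baseline_hazard = baseline_hazard, censor_max = censor_max,
                 high_fraction = high_fraction, tpm_cutoff = tpm_cutoff,
                 effect_phenotype = effect_phenotype,
                 n_background_genes = as.integer(n_background_genes),
                 drug_params = drug_params, dep_params = dep_params,
                 qpcr_params = qpcr_params),
            class = "sim_config")
}

# Draw an n x 2 matrix of standard normals with the given correlation.
rbvn <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

tpm_from_log2 <- function(x) pmax(2^x - 1, 0)

marker_feature_ids <- function(panel = marker_panel()) {
  c(panel$mesenchymal, panel$epithelial)
}

#' Simulate a tumor expression + clinical cohort
#'
#' Generates a cohort with correlated KRAB / KRAB-less isoform expression,
#' 14 EMT markers driven by two correlated latent epithelial/mesenchymal
#' axes, and exponential survival times with uniform administrative censoring
#' where the log hazard is `true_log_hr` for samples whose KRAB-isoform TPM
#' is at or above the cutoff (optionally restricted to one latent phenotype).
#' A stromal-score column correlated with the mesenchymal axis is included in
#' the clinical table.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (samples x features TPM matrix including
#'   the 14 markers, `ZNF71_overall`, `ZNF71_KRAB`, `ZNF71_KRABless`),
#'   `clinical` (sample_id, time, event, stage, histology, stromal_score) and
#'   `truth` (latent axes, latent phenotype, high/low group) — the truth
#'   sidecar is never read by any analysis operation.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_tumors
  ids <- sprintf("T%03d", seq_len(n))

  # isoforms on log2 scale, bivariate with iso_corr_rho
  z <- rbvn(n, config$iso_corr_rho)
  x_krab <- config$krab_logmean + config$logsd * z[, 1]
  x_krabless <- config$krabless_logmean + config$logsd * z[, 2]
  tpm_krab <- tpm_from_log2(x_krab)
  tpm_krabless <- tpm_from_log2(x_krabless)
  high <- tpm_krab >= config$tpm_cutoff

  # latent EMT axes and markers
  ax <- rbvn(n, config$emt_axis_corr)
  epi_axis <- ax[, 1]
  mes_axis <- ax[, 2]
  panel <- marker_panel()
  marker_mat <- sapply(marker_feature_ids(panel), function(m) {
    axis <- if (m %in% panel$mesenchymal) mes_axis else epi_axis
    tpm_from_log2(config$marker_baseline + config$marker_loading * axis +
                    stats::rnorm(n, 0, config$noise_sd))
  })
  latent_pheno <- quadrant_label(above_median(mes_axis),
                                 above_median(epi_axis))

  expr <- cbind(marker_mat,
                ZNF71_KRAB = tpm_krab,
                ZNF71_KRABless = tpm_krabless,
                ZNF71_overall = tpm_krab + tpm_krabless)
  rownames(expr) <- ids

  # survival: exponential times, planted log-HR on the high group
  eff <- high
  if (!is.null(config$effect_phenotype))
    eff <- high & latent_pheno == config$effect_phenotype
  rate <- config$baseline_hazard * exp(config$true_log_hr * eff)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, config$censor_max)
  clinical <- data.frame(
    sample_id = ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.35, 0.30, 0.25, 0.10)),
    histology = sample(c("adenocarcinoma", "squamous", "large_cell"), n,
                       replace = TRUE, prob = c(0.55, 0.35, 0.10)),
    stromal_score = 600 * mes_axis + stats::rnorm(n, 0, 300),
    stringsAsFactors = FALSE)

  truth <- data.frame(sample_id = ids, epi_axis = epi_axis,
                      mes_axis = mes_axis,
                      phenotype = as.character(latent_pheno),
                      high_krab = high, effect_group = eff,
                      stringsAsFactors = FALSE)
  validate_expression_matrix(expr)
  validate_clinical_table(clinical)
  list(expression = expr, clinical = clinical, truth = truth)
}

#' Simulate a cell-line panel: expression, drug response, gene effects
#'
#' Cell-line expression follows the same isoform/marker model as the tumor
#' cohort plus `n_background_genes` null genes.  For each drug, a latent
#' standard-normal severity draw determines both the log-IC50/EC50 values and
#' a hidden resistant (z > 0.5) / sensitive (z < -0.5) / partial label; the
#' drug's planted log2 expression shift is added to its `shift_genes` in
#' hidden-resistant lines.  The dependency panel draws raw gene effects for
#' labeled essential and non-essential controls plus query genes.
#'
#' @param config a [sim_config()] with at least one drug in `drug_params`.
#' @return list with `expression` (matrix), `drug_response` (long
#'   data.frame: cell_line, drug, ic50, ec50), `dependency` (long data.frame:
#'   cell_line, gene, raw_effect, control_label) and `truth` (hidden response
#'   labels per drug).
#' @export
simulate_cell_lines <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (length(config$drug_params) < 1)
    config_error("drug_params must contain at least one drug")
  set.seed(config$seed)
  n <- config$n_cell_lines
  ids <- sprintf("CL%03d", seq_len(n))
  panel <- marker_panel()

  z <- rbvn(n, config$iso_corr_rho)
  x <- cbind(ZNF71_KRAB = config$krab_logmean + config$logsd * z[, 1],
             ZNF71_KRABless = config$krabless_logmean + config$logsd * z[, 2])
  ax <- rbvn(n, config$emt_axis_corr)
  for (m in marker_feature_ids(panel)) {
    axis <- if (m %in% panel$mesenchymal) ax[, 2] else ax[, 1]
    x <- cbind(x, config$marker_baseline + config$marker_loading * axis +
                 stats::rnorm(n, 0, config$noise_sd))
    colnames(x)[ncol(x)] <- m
  }
  if (config$n_background_genes > 0) {
    bg <- matrix(stats::rnorm(n * config$n_background_genes, 3, 1), nrow = n)
    colnames(bg) <- sprintf("BG%04d", seq_len(config$n_background_genes))
    x <- cbind(x, bg)
  }

  # drug response: shared severity draw for ic50/ec50 + hidden labels
  drugs <- names(config$drug_params)
  dr <- vector("list", length(drugs))
  hidden <- vector("list", length(drugs))
  for (k in seq_along(drugs)) {
    p <- config$drug_params[[drugs[k]]]
    zk <- stats::rnorm(n)
    zk_ec <- 0.9 * zk + sqrt(1 - 0.81) * stats::rnorm(n)
    label <- ifelse(zk > 0.5, "resistant",
                    ifelse(zk < -0.5, "sensitive", "partial"))
    dr[[k]] <- data.frame(cell_line = ids, drug = drugs[k],
                          ic50 = p$ic50_logmean + p$ic50_logsd * zk,
                          ec50 = p$ec50_logmean + p$ec50_logsd * zk_ec,
                          stringsAsFactors = FALSE)
    hidden[[k]] <- data.frame(cell_line = ids, drug = drugs[k],
                              hidden_label = label, stringsAsFactors = FALSE)
    if (length(p$shift_genes) > 0 && p$shift != 0) {
      shift_cols <- intersect(p$shift_genes, colnames(x))
      x[label == "resistant", shift_cols] <-
        x[label == "resistant", shift_cols] + p$shift
    }
  }
  expr <- apply(x, 2, tpm_from_log2)
  expr <- cbind(expr,
                ZNF71_overall = expr[, "ZNF71_KRAB"] + expr[, "ZNF71_KRABless"])
  rownames(expr) <- ids

  # dependency panel
  dp <- config$dep_params
  genes <- c(sprintf("ESS%03d", seq_len(dp$n_essential)),
             sprintf("NE%03d", seq_len(dp$n_nonessential)),
             dp$query_genes)
  labels <- c(rep("essential", dp$n_essential),
              rep("non_essential", dp$n_nonessential),
              rep("query", length(dp$query_genes)))
  means <- c(rep(dp$essential_mean, dp$n_essential),
             rep(dp$noness_mean, dp$n_nonessential),
             rep(dp$query_mean, length(dp$query_genes)))
  sds <- c(rep(dp$essential_sd, dp$n_essential),
           rep(dp$noness_sd, dp$n_nonessential),
           rep(dp$query_sd, length(dp$query_genes)))
  dep <- data.frame(
    cell_line = rep(ids, each = length(genes)),
    gene = rep(genes, times = n),
    raw_effect = stats::rnorm(n * length(genes), mean = rep(means, times = n),
                              sd = rep(sds, times = n)),
    control_label = rep(labels, times = n),
    stringsAsFactors = FALSE)

  validate_expression_matrix(expr)
  list(expression = expr,
       drug_response = do.call(rbind, dr),
       dependency = dep,
       truth = do.call(rbind, hidden))
}

#' Simulate a triplicate qPCR plate
#'
#' One target and one housekeeping assay per sample, in triplicate, with
#' Gaussian technical noise of SD `tech_sd` per well.  The first sample is
#' the reference; each sample's planted ddCt (relative to the reference,
#' housekeeping held flat) defaults to N(0, 1) draws with the reference at 0.
#'
#' @param config a [sim_config()].
#' @return a `qpcr_plate` data.frame (`sample_id`, `target`, `role`,
#'   `rep1..rep3`) with attributes `reference_sample_id` and `planted_ddct`.
#' @export
simulate_qpcr <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  qp <- config$qpcr_params
  n <- qp$n_samples
  ids <- sprintf("S%02d", seq_len(n))
  ddct <- qp$ddct
  if (is.null(ddct)) ddct <- c(0, stats::rnorm(n - 1))
  if (ddct[1] != 0)
    config_error("planted ddct of the reference (first) sample must be 0")
  rows <- list()
  for (i in seq_len(n)) {
    rows[[2 * i - 1]] <- data.frame(
      sample_id = ids[i], target = qp$target, role = "target",
      rep1 = qp$base_ct + ddct[i] + stats::rnorm(1, 0, qp$tech_sd),
      rep2 = qp$base_ct + ddct[i] + stats::rnorm(1, 0, qp$tech_sd),
      rep3 = qp$base_ct + ddct[i] + stats::rnorm(1, 0, qp$tech_sd),
      stringsAsFactors = FALSE)
    rows[[2 * i]] <- data.frame(
      sample_id = ids[i], target = qp$housekeeping, role = "housekeeping",
      rep1 = qp$hk_ct + stats::rnorm(1, 0, qp$tech_sd),
      rep2 = qp$hk_ct + stats::rnorm(1, 0, qp$tech_sd),
      rep3 = qp$hk_ct + stats::rnorm(1, 0, qp$tech_sd),
      stringsAsFactors = FALSE)
  }
  plate <- do.call(rbind, rows)
  attr(plate, "reference_sample_id") <- ids[1]
  attr(plate, "planted_ddct") <- stats::setNames(ddct, ids)
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}
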