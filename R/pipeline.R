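# End-to-end orchestration: simulate or load inputs, classify EMT quadrants,
# run overall and per-phenotype cutoff survival analyses, categorize drug
# response with differential expression, normalize and call dependencies,
# and quantify qPCR fold changes.  Pure function of (config, seed): reruns
# produce byte-identical reports.

#' Run the full analysis pipeline
#'
#' @param config config list (see [read_run_config()]) or a path to a
#'   YAML/JSON config file.
#' @param out_dir output directory, created if needed.  Writes
#'   `emt_calls.tsv`, `survival_report.json`, `drug_response.tsv`,
#'   `drug_diffexpr.tsv`, `dependency_calls.tsv`, `qpcr_foldchanges.tsv`
#'   (when a plate is given or simulated) and `run.log`.
#' @return invisibly, the list of result objects.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$simulate) && is.null(config$expression))
    config_error("config must contain a 'simulate' block or an 'expression' path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("emtquad version: %s",
                         as.character(utils::packageVersion("emtquad"))),
                 sprintf("seed: %s", config$seed),
                 sprintf("feature: %s | cutoff: %s | drug_metric: %s | dependency_threshold: %s",
                         config$feature, config$cutoff, config$drug_metric,
                         config$dependency_threshold))

  cells <- NULL; plate <- NULL; drugs <- NULL; dep <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg)
    cells <- simulate_cell_lines(scfg)
    plate <- simulate_qpcr(scfg)
    expr <- cohort$expression
    clinical <- cohort$clinical
    drugs <- cells$drug_response
    dep <- cells$dependency
    log_lines <- c(log_lines, "inputs: simulated",
                   sprintf("n_tumors: %d | n_cell_lines: %d",
                           scfg$n_tumors, scfg$n_cell_lines))
  } else {
    expr <- read_expression_table(config$expression)
    clinical <- read_clinical_table(config$clinical)
    if (!is.null(config[["drugs"]])) drugs <- read_drug_table(config[["drugs"]])
    if (!is.null(config[["dependency"]]))
      dep <- read_dependency_table(config[["dependency"]])
    if (!is.null(config[["qpcr"]])) plate <- read_qpcr_plate(config[["qpcr"]])
    if (!is.null(config[["cell_expression"]]))
      cells <- list(expression = read_expression_table(config[["cell_expression"]]))
    log_lines <- c(log_lines, "inputs: files")
  }

  # join policy: analyses run on the intersection of expression/clinical ids
  common <- intersect(rownames(expr), clinical$sample_id)
  dropped <- (nrow(expr) - length(common)) +
    (nrow(clinical) - length(common))
  if (length(common) < 4)
    insufficient_error("fewer than 4 samples shared between expression and clinical")
  log_lines <- c(log_lines,
                 sprintf("samples: %d shared, %d dropped in join",
                         length(common), dropped))
  expr <- expr[common, , drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), ]

  # EMT classification
  calls <- classify_emt_quadrants(expr)
  write_tsv_num(as.data.frame(calls), file.path(out_dir, "emt_calls.tsv"))

  # survival: overall cutoff stratification + per phenotype
  vals <- get_features(expr, config$feature)[, 1]
  strat <- stratify_by_cutoff(vals, config$cutoff)
  overall <- list(
    n_high = sum(strat == "high"), n_low = sum(strat == "low"),
    high_fraction = attr(strat, "high_fraction"))
  if (overall$n_high > 0 && overall$n_low > 0 && sum(clinical$event) > 0) {
    lr <- logrank_test(clinical$time, clinical$event, strat)
    hr <- tryCatch(hazard_ratio(clinical$time, clinical$event, strat,
                                reference = "low"),
                   emtquad_nonestimable_error = function(e) NULL)
    overall$logrank_stat <- lr$statistic
    overall$logrank_p <- lr$p
    if (!is.null(hr))
      overall[c("hr", "hr_lo", "hr_hi")] <- hr[c("hr", "ci_lo", "ci_hi")]
    overall$km <- lapply(split(seq_along(strat), strat), function(idx)
      km_estimate(clinical$time[idx], clinical$event[idx]))
  }
  pheno_surv <- per_phenotype_survival(expr, clinical, calls, config$feature,
                                       config$cutoff)
  report <- list(feature = config$feature, cutoff = config$cutoff,
                 overall = overall, by_phenotype = pheno_surv,
                 phenotype_logrank =
                   logrank_test(clinical$time, clinical$event,
                                calls$phenotype)[c("statistic", "df", "p")])
  jsonlite::write_json(report, file.path(out_dir, "survival_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")

  # drug response
  if (!is.null(drugs)) {
    out_dr <- drugs
    out_dr$category_ic50 <- NA_character_
    out_dr$category_ec50 <- NA_character_
    de_rows <- list()
    features <- intersect(c("ZNF71_overall", "ZNF71_KRAB", "ZNF71_KRABless"),
                          colnames(if (!is.null(cells)) cells$expression else expr))
    for (d in unique(drugs$drug)) {
      idx <- which(out_dr$drug == d)
      for (metric in intersect(c("ic50", "ec50"), names(drugs))) {
        v <- stats::setNames(out_dr[[metric]][idx], out_dr$cell_line[idx])
        if (sum(is.finite(v)) < 3) next
        cat_col <- paste0("category_", metric)
        cats <- categorize_response(v)
        out_dr[[cat_col]][idx] <- cats
        if (!is.null(cells) && length(features) > 0) {
          de <- diff_expr_by_response(cells$expression, cats,
                                      features = features)
          de$drug <- d
          de$metric <- metric
          de_rows[[paste(d, metric)]] <- de
        }
      }
    }
    write_csv_num(out_dr, file.path(out_dir, "drug_response.tsv"))
    if (length(de_rows) > 0)
      write_tsv_num(do.call(rbind, de_rows),
                    file.path(out_dir, "drug_diffexpr.tsv"))
  }

  # dependency
  if (!is.null(dep)) {
    ndep <- normalize_dependency_panel(dep)
    ndep$call <- ifelse(ndep$normalized_effect <= config$dependency_threshold,
                        "dependent", "not_dependent")
    write_tsv_num(ndep, file.path(out_dir, "dependency_calls.tsv"))
    q <- ndep[ndep$control_label == "query", ]
    if (nrow(q) > 0) {
      verd <- call_dependency(q$normalized_effect,
                              config$dependency_threshold)
      log_lines <- c(log_lines,
                     sprintf("query dependency verdict: %s", verd$verdict))
    }
  }

  # qPCR
  if (!is.null(plate)) {
    fc <- ddct_fold_change(plate)
    write_tsv_num(fc, file.path(out_dir, "qpcr_foldchanges.tsv"))
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(calls = calls, survival = report))
}

# Deterministic numeric formatting (15 significant digits) so reruns are
# byte-identical across platforms.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                        formatC(df[[j]], digits = 15, format = "g"))
  }
  df
}

write_tsv_num <- function(df, path) {
  utils::write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

write_csv_num <- function(df, path) {
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   na = "")
}
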