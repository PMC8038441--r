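test_that("expression table round-trips through TSV", {
  co <- simulate_cohort(sim_config(seed = 11, n_tumors = 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(co$expression, path)
  back <- read_expression_table(path)
  expect_identical(rownames(back), rownames(co$expression))
  expect_identical(colnames(back), colnames(co$expression))
  expect_equal(back, co$expression, tolerance = 1e-12)
})

test_that("expression reader reports offending cells with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tG1\tG2", "s1\t1.0\t2.0", "s2\t-0.5\t1.0"), path)
  expect_error(read_expression_table(path), "s2.*G1",
               class = "emtquad_format_error")

  writeLines(c("sample_id\tG1\tG2", "s1\t1.0\tabc", "s2\t0.5\t1.0"), path)
  expect_error(read_expression_table(path), "G2",
               class = "emtquad_format_error")

  writeLines(c("sample_id\tG1", "s1\t1.0", "s1\t2.0"), path)
  expect_error(read_expression_table(path), "duplicate",
               class = "emtquad_format_error")
})

test_that("clinical table round-trips and rejects invalid rows", {
  co <- simulate_cohort(sim_config(seed = 12, n_tumors = 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical_table(co$clinical, path)
  back <- read_clinical_table(path)
  expect_equal(back$sample_id, co$clinical$sample_id)
  expect_equal(back$time, co$clinical$time, tolerance = 1e-12)
  expect_equal(back$event, co$clinical$event)
  expect_equal(back$stage, co$clinical$stage)

  bad <- co$clinical
  bad$event[3] <- 2
  expect_error(validate_clinical_table(bad), "binary",
               class = "emtquad_format_error")
  bad2 <- co$clinical[, c("sample_id", "time")]
  expect_error(validate_clinical_table(bad2), "event",
               class = "emtquad_format_error")
})

test_that("drug, dependency and qPCR tables round-trip with their dialects", {
  cl <- simulate_cell_lines(sim_config(seed = 13, n_cell_lines = 10))

  dpath <- withr::local_tempfile(fileext = ".csv")
  write_drug_table(cl$drug_response, dpath)
  dr <- read_drug_table(dpath)
  expect_equal(dr$ic50, cl$drug_response$ic50, tolerance = 1e-12)
  expect_equal(dr$cell_line, cl$drug_response$cell_line)

  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_dependency_table(cl$dependency, ppath)
  dep <- read_dependency_table(ppath)
  expect_equal(dep$raw_effect, cl$dependency$raw_effect, tolerance = 1e-12)
  expect_equal(dep$control_label, cl$dependency$control_label)

  plate <- simulate_qpcr(sim_config(seed = 13))
  qpath <- withr::local_tempfile(fileext = ".csv")
  write_qpcr_plate(plate, qpath)
  back <- read_qpcr_plate(qpath)
  expect_equal(attr(back, "reference_sample_id"),
               attr(plate, "reference_sample_id"))
  expect_equal(back$rep1, plate$rep1, tolerance = 1e-12)
  expect_equal(
    ddct_fold_change(back)$fold_change,
    ddct_fold_change(plate)$fold_change, tolerance = 1e-10)
})

test_that("run config loads from YAML and JSON with validation", {
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "simulate:", "  n_tumors: 40",
               "feature: ZNF71_KRAB"), ypath)
  cfg <- read_run_config(ypath)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$simulate$n_tumors, 40)
  expect_equal(cfg$cutoff, 1.5)

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 3, "simulate": {"n_tumors": 20}}', jpath)
  cfgj <- read_run_config(jpath)
  expect_equal(cfgj$seed, 3)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 5", bad)
  expect_error(read_run_config(bad), class = "emtquad_config_error")
})

test_that("pipeline joins on the intersection of sample ids", {
  co <- simulate_cohort(sim_config(seed = 14, n_tumors = 30))
  dir <- withr::local_tempdir()
  epath <- file.path(dir, "expr.tsv")
  cpath <- file.path(dir, "clin.tsv")
  # 5-sample expression, clinical with 1 mismatching id
  write_expression_table(co$expression[1:5, ], epath)
  clin <- co$clinical[1:5, ]
  clin$sample_id[5] <- "NOT_PRESENT"
  write_clinical_table(clin, cpath)
  out <- file.path(dir, "out")
  run_pipeline(list(expression = epath, clinical = cpath, seed = 1,
                    feature = "ZNF71_KRAB", cutoff = 1.5,
                    drug_metric = "ic50", dependency_threshold = -0.5),
               out)
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("4 shared, 2 dropped", log)))
  calls <- read.delim(file.path(out, "emt_calls.tsv"))
  expect_equal(nrow(calls), 4)

  # intersection below 4 is a hard error
  clin2 <- co$clinical[8:30, ]
  write_clinical_table(clin2, cpath)
  expect_error(
    run_pipeline(list(expression = epath, clinical = cpath, seed = 1,
                      feature = "ZNF71_KRAB", cutoff = 1.5,
                      drug_metric = "ic50", dependency_threshold = -0.5),
                 file.path(dir, "out2")),
    class = "emtquad_insufficient_error")
})

test_that("simulated pipeline run writes every artifact deterministically", {
  dir <- withr::local_tempdir()
  cfgpath <- file.path(dir, "cfg.yaml")
  writeLines(c("seed: 7", "simulate:", "  n_tumors: 60",
               "  n_cell_lines: 30"), cfgpath)
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  run_pipeline(cfgpath, out1)
  run_pipeline(cfgpath, out2)
  arts <- c("emt_calls.tsv", "survival_report.json", "drug_response.tsv",
            "drug_diffexpr.tsv", "dependency_calls.tsv",
            "qpcr_foldchanges.tsv", "run.log")
  for (a in arts) {
    expect_true(file.exists(file.path(out1, a)), info = a)
    expect_identical(readLines(file.path(out1, a)),
                     readLines(file.path(out2, a)), info = a)
  }
})
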