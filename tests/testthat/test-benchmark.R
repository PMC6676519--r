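# End-to-end benchmark runs, arm comparisons, figure-table export.

small_run_config <- function(seed = 7, n_sets = 60, arms = "unmatched",
                             case_definitions = "AD_vs_CTL") {
  list(
    run_id = "test_run",
    seed = seed,
    sim = list(n_cohorts = 2, n_cases = 40, n_controls = 40, g_total = 800,
               n_signal = 60, n_background = 120, n_age_genes = 20,
               n_sex_genes = 10, effect_size = 1),
    candidate = "planted",
    case_definitions = case_definitions,
    arms = arms,
    schemes = list(
      list(name = "within75", mode = "within", split_fraction = 0.75,
           n_repeats = 5, cohort = "cohort1"),
      list(name = "cross12", mode = "cross", train_cohort_id = "cohort1",
           test_cohort_ids = list("cohort2"))),
    pools = list(
      list(name = "all1", type = "all", cohort = "cohort1"),
      list(name = "flt1", type = "filtered", cohort = "cohort1",
           exclusion = "planted")),
    null = list(set_size = 60, n_sets = n_sets),
    alpha = 0.05)
}

test_that("a full benchmark run produces coherent cells and checklist", {
  report <- run_benchmark(small_run_config())
  expect_s3_class(report, "BenchmarkReport")
  expect_length(report$cells, 4L) # 2 schemes x 1 case-def x 1 arm x 2 pools

  tab <- benchmark_cell_table(report)
  expect_true(all(tab$candidate_auc >= 0 & tab$candidate_auc <= 1))
  expect_true(all(tab$empirical_p >= 1 / (tab$n_null + 1)))
  expect_true(all(tab$bh_p >= tab$empirical_p - 1e-12))

  # a clearly planted candidate ranks first against its null in cross mode
  cross_cells <- tab[tab$mode == "cross", ]
  expect_true(any(cross_cells$rank == 1))

  # checklist booleans recompute from the cells alone (no hidden state)
  cl <- report$checklist
  expect_equal(cl$external_validation_done, any(tab$mode == "cross"))
  expect_equal(cl$matched_design_used, any(tab$arm == "matched"))
  expect_equal(cl$mci_excluded, any(tab$case_definition == "AD_vs_CTL"))
  expect_true(cl$multiple_testing_corrected)
  expect_true(cl$external_validation_done)
  expect_false(cl$matched_design_used)
  cross_rep <- vapply(report$cells[tab$mode == "cross"],
                      function(c_) isTRUE(c_$significance$replicated_all_cohorts), TRUE)
  expect_equal(cl$significant_in_all_test_cohorts, any(cross_rep))
})

test_that("misconfigured runs abort with the failing stage named", {
  bad <- small_run_config()
  bad$sim <- NULL
  expect_error(run_benchmark(bad), "stage 'config'")
  bad2 <- small_run_config()
  bad2$candidate <- "/nonexistent/signature.tsv"
  expect_error(run_benchmark(bad2), "stage 'candidate'")
})

test_that("identical config and master seed reproduce the report exactly", {
  cfg <- small_run_config(n_sets = 30)
  r1 <- run_benchmark(cfg)
  r2 <- run_benchmark(cfg)
  expect_identical(benchmark_cell_table(r1), benchmark_cell_table(r2))
  expect_identical(lapply(r1$cells, `[[`, "null"),
                   lapply(r2$cells, `[[`, "null"))

  d1 <- tempfile(); d2 <- tempfile()
  write_benchmark_report(r1, d1)
  write_benchmark_report(r2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # reports are append-only: refusing to overwrite a populated directory
  expect_error(write_benchmark_report(r1, d1), "not empty")
})

test_that("compare_arms pairs cells correctly and handles degenerate requests", {
  report <- run_benchmark(small_run_config(n_sets = 30))
  # comparing an arm with itself: all deltas exactly zero
  self <- compare_arms(report, "all1", "all1")
  expect_true(all(self$d_candidate_auc == 0))
  expect_true(all(self$d_null_mean == 0))
  expect_true(all(self$d_margin == 0))

  # all-genes vs exclusion-filtered pools: same candidate, different nulls
  pools <- compare_arms(report, "all1", "flt1")
  expect_equal(nrow(pools), 2L) # one pair per scheme
  expect_true(all(pools$d_candidate_auc == 0))

  expect_error(compare_arms(report, "absent_arm", "all1"), "matches no cell")
  expect_error(compare_arms(report, "within75", "all1"), "different components")
})

test_that("unmatched designs inflate an age-driven candidate relative to matched", {
  # cases 8 years older; candidate carries only age biology (no disease genes)
  cfg <- list(
    run_id = "age_conf", seed = 11,
    sim = list(n_cohorts = 2, n_cases = 40, n_controls = 60, g_total = 800,
               n_signal = 30, n_background = 120, n_age_genes = 30,
               n_sex_genes = 5, effect_size = 0, case_age_shift = 8,
               age_slope = 0.5),
    candidate = NULL, # filled below
    case_definitions = "AD_vs_CTL",
    arms = c("unmatched", "matched"),
    matching = list(age_tolerance = 5),
    schemes = list(list(name = "cross12", mode = "cross",
                        train_cohort_id = "cohort1",
                        test_cohort_ids = list("cohort2"))),
    pools = list(list(name = "all1", type = "all", cohort = "cohort1")),
    null = list(set_size = 30, n_sets = 20))
  # write the age-gene signature (ground truth directions) as the candidate
  simc <- do.call(sim_config, c(cfg$sim, list(seed = derive_seed(11, "sim"))))
  gt <- sim_gene_table(simc)
  age_genes <- gt[gt$role == "age", ]
  sig_path <- tempfile(fileext = ".tsv")
  write_signature(directional_signature("age_candidate", age_genes$gene_id,
                                        sign(age_genes$age_slope)), sig_path)
  cfg$candidate <- sig_path
  report <- run_benchmark(cfg)
  delta <- compare_arms(report, "unmatched", "matched")
  expect_true(all(delta$d_candidate_auc >= 0))
  expect_true(report$checklist$matched_design_used)
})

test_that("figure tables carry every null plus one flagged candidate row", {
  report <- run_benchmark(small_run_config(n_sets = 30))
  key <- names(report$cells)[1]
  df <- export_figure_table(report, key)
  cell <- report$cells[[key]]
  expect_equal(nrow(df), length(cell$null$aucs) + 1L)
  expect_equal(sum(df$is_candidate), 1L)
  expect_equal(df$auc[df$is_candidate == 1], cell$candidate$mean_auc)
  # sorted nulls reproduce the cell's summary percentiles
  expect_equal(unname(quantile(df$auc[df$is_candidate == 0], 0.95)),
               cell$null_summary$p95)
  expect_error(export_figure_table(report, "no|such|cell"), "not present")

  out <- tempfile(fileext = ".tsv")
  export_figure_table(report, key, out)
  expect_equal(nrow(read.delim(out)), nrow(df))
})

test_that("yaml configs load equivalently to in-memory configs", {
  cfg <- small_run_config(n_sets = 20)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  expect_identical(benchmark_cell_table(run_benchmark(path)),
                   benchmark_cell_table(run_benchmark(cfg)))
})
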