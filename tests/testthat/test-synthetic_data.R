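# The synthetic multi-cohort generator: planted signal, background stratum,
# batch-class confounding, demographics, determinism.

test_that("config invariants are enforced", {
  expect_error(sim_config(n_signal = 1500, n_background = 1000, g_total = 2000),
               "exceeds g_total")
  expect_error(sim_config(overlap = 0.2), "core")
  expect_error(sim_config(batch_class_cor = 1.5), "batch_class_cor")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("planted signature exposes ground truth consistent with the gene table", {
  cfg <- sim_config(n_signal = 150, seed = 71)
  sig <- planted_signature(cfg)
  expect_length(sig$gene_ids, 150)
  gt <- sim_gene_table(cfg)
  expect_setequal(sig$gene_ids, gt$gene_id[gt$role == "signal"])
  expect_equal(sig$directions,
               gt$direction[match(sig$gene_ids, gt$gene_id)])
  expect_length(intersect(sig$gene_ids, gt$gene_id[gt$role == "background"]), 0)
})

test_that("a pure-noise configuration carries no class signal", {
  cfg <- sim_config(n_cohorts = 1, effect_size = 0, batch_sd = 0,
                    age_slope = 0, sex_effect = 0, case_age_shift = 0, seed = 73)
  sim <- generate_cohorts(cfg)[[1]]
  labels <- select_diagnosis_groups(sim$metadata, "AD_vs_CTL")
  sv <- directional_score(sim$cohort, planted_signature(cfg))
  a <- auc(sv, labels)$auc
  # AUC sd under H0 is ~ sqrt((n1+n0+1)/(12 n1 n0)) ~ 0.053 at 60v60
  expect_lt(abs(a - 0.5), 4 * sqrt(121 / (12 * 3600)))
})

test_that("generated moments match the config within standard-error bounds", {
  cfg <- sim_config(n_cohorts = 1, effect_size = 0, batch_sd = 0, noise_sd = 1,
                    case_age_shift = 0, age_slope = 0, sex_effect = 0,
                    mu_bg = 4, sd_bg = 0, seed = 75)
  sim <- generate_cohorts(cfg)[[1]]
  gt <- sim_gene_table(cfg)
  bg <- gt$gene_id[gt$role == "background"]
  bg_vals <- sim$cohort$values[bg, ]
  expect_lt(abs(mean(bg_vals) - 4), 4 / sqrt(length(bg_vals)))
  # per-value sd should match noise_sd
  expect_lt(abs(sd(bg_vals) - 1), 0.02)
})

test_that("MCI samples with zero mixing are controls in expectation", {
  cfg <- sim_config(n_cohorts = 1, n_mci = 60, mci_mixing = 0, batch_sd = 0,
                    case_age_shift = 0, seed = 77)
  sim <- generate_cohorts(cfg)[[1]]
  sig_genes <- planted_signature(cfg)$gene_ids
  md <- sim$metadata
  mci_cols <- md$sample_id[md$diagnosis == "MCI"]
  ctl_cols <- md$sample_id[md$diagnosis == "CTL"]
  ad_cols <- md$sample_id[md$diagnosis == "AD"]
  X <- sim$cohort$values[sig_genes, ]
  d_mci <- mean(abs(rowMeans(X[, mci_cols]) - rowMeans(X[, ctl_cols])))
  d_ad <- mean(abs(rowMeans(X[, ad_cols]) - rowMeans(X[, ctl_cols])))
  expect_lt(d_mci, 0.4 * d_ad) # AD shifted by d = 0.8, MCI not shifted at all
})

test_that("platform universes share the core and differ in the remainder", {
  cfg <- sim_config(n_cohorts = 2, overlap = 0.8, seed = 79)
  sims <- generate_cohorts(cfg)
  gt <- sim_gene_table(cfg)
  core <- gt$gene_id[gt$core]
  g1 <- sims[[1]]$cohort$gene_ids
  g2 <- sims[[2]]$cohort$gene_ids
  expect_true(all(core %in% g1) && all(core %in% g2))
  expect_gt(length(setdiff(g1, g2)), 0)
  expect_gt(length(setdiff(g2, g1)), 0)
})

test_that("cohort generation is bit-reproducible and responsive to seed", {
  cfg <- sim_config(n_cohorts = 2, seed = 81)
  a <- generate_cohorts(cfg)
  b <- generate_cohorts(cfg)
  expect_identical(a, b)
  c_ <- generate_cohorts(sim_config(n_cohorts = 2, seed = 82))
  expect_false(identical(a[[1]]$cohort$values, c_[[1]]$cohort$values))
})

test_that("planted cross-cohort AUC increases with effect size", {
  aucs <- vapply(c(0, 0.5, 1, 2), function(d) {
    cfg <- sim_config(n_cohorts = 2, effect_size = d, case_age_shift = 0,
                      batch_sd = 0, batch_class_cor = 0, seed = 83)
    sims <- generate_cohorts(cfg)
    cohorts <- stats::setNames(lapply(sims, `[[`, "cohort"), c("cohort1", "cohort2"))
    labels <- stats::setNames(
      lapply(sims, function(s) select_diagnosis_groups(s$metadata, "AD_vs_CTL")),
      names(cohorts))
    cross_cohort_validate(cohorts, labels, planted_signature(cfg),
                          scheme_config("cross", train_cohort_id = "cohort1",
                                        test_cohort_ids = "cohort2", seed = 1))$mean_auc
  }, 0)
  # strictly increasing until the AUC saturates at 1
  expect_true(all(diff(aucs) >= 0))
  expect_gt(aucs[4], aucs[1])
  expect_lt(abs(aucs[1] - 0.5), 0.1)
  expect_gt(aucs[4], 0.99)
})

test_that("full batch-class confounding lets background sets classify within-cohort", {
  # all cases in batch 1, controls spread over 4 batches: batch nearly
  # identifies class, and the batch shifts dwarf biological noise
  cfg <- sim_config(n_cohorts = 1, effect_size = 0, batch_sd = 3, noise_sd = 0.5,
                    n_batches = 4, batch_class_cor = 1, case_age_shift = 0,
                    seed = 85)
  sim <- generate_cohorts(cfg)[[1]]
  labels <- select_diagnosis_groups(sim$metadata, "AD_vs_CTL")
  bg_pool <- background_pool(sim$cohort)
  sets <- sample_gene_sets(sampling_config(bg_pool, 100, 20, seed = 2))
  nulls <- evaluate_null(sets, sim$cohort, labels,
                         scheme_config("within", 0.75, 4, seed = 3))
  expect_gt(mean(nulls$aucs), 0.8)
})

test_that("fixture bundles are complete, checksummed and seed-stable", {
  cfg <- sim_config(n_cohorts = 2, n_cases = 10, n_controls = 10, g_total = 300,
                    n_signal = 20, n_background = 40, n_age_genes = 5,
                    n_sex_genes = 5, seed = 87)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  m1 <- write_fixture_bundle(cfg, d1)
  m2 <- write_fixture_bundle(cfg, d2)
  files <- vapply(m1$files, `[[`, "", "path")
  expect_setequal(files, c("cohort1_expression.tsv", "cohort2_expression.tsv",
                           "metadata.tsv", "planted_signature.tsv",
                           "exclusion_planted.txt", "gene_sets.gmt"))
  # manifest checksums match the files on disk, and reruns are byte-identical
  for (f in m1$files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f$path))), f$md5)
  }
  expect_equal(lapply(m1$files, `[[`, "md5"), lapply(m2$files, `[[`, "md5"))

  # the bundle reloads through the package's own readers
  co <- read_expression_cohort(file.path(d1, "cohort1_expression.tsv"), "cohort1")
  md <- read_sample_metadata(file.path(d1, "metadata.tsv"))
  sig <- read_signature(file.path(d1, "planted_signature.tsv"))
  excl <- read_exclusion_list(file.path(d1, "exclusion_planted.txt"))
  gmt <- read_gmt(file.path(d1, "gene_sets.gmt"))
  expect_equal(sort(sig$gene_ids), sort(excl))
  expect_setequal(gmt$planted, sig$gene_ids)
  expect_true(all(md$sample_id[md$cohort_id == "cohort1"] %in% co$sample_ids))
})
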