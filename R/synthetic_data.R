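# Synthetic multi-cohort expression generator. Emulates the statistical
# structure the benchmark depends on: planted directional signal, a stratum of
# below-detection background probes, batch effects (hitting ALL genes,
# background included) optionally confounded with class, age- and
# sex-structured risk with cases older than controls, a clinically mixed MCI
# group, and two platforms with partially overlapping gene universes.

#' Simulation configuration
#'
#' Gaussian log2-intensity model (microarray-like). For gene g and sample s:
#' \deqn{y_{gs} = \mu_g + d\,dir_g\,signal_s 1[g \in S] + \beta_g (age_s - \bar{age})/10
#'   + \gamma_g 1[s\ male] + b_{batch(s),g} + \epsilon_{gs}}
#' with `signal_s` = 1 for AD cases, Bernoulli(`mci_mixing`) for MCI, 0 for
#' controls; batch effects `b ~ N(0, batch_sd^2)` drawn per gene per batch and
#' applied to every gene including background; noise `e ~ N(0, noise_sd^2)`.
#' Background genes sit at the detection floor `mu_bg` and carry no signal,
#' age or sex terms — any class signal they show is technical. With
#' `batch_class_cor` rho > 0, a fraction rho of cases is forced into batch 1,
#' confounding batch with class. Cases are drawn `case_age_shift` years older
#' than controls so that skipping age matching measurably helps an age-driven
#' signature.
#'
#' @param n_cohorts number of cohorts (default 2).
#' @param n_cases,n_controls,n_mci per-cohort sample counts (scalar or
#'   per-cohort vector; defaults 60/60/0).
#' @param g_total total gene universe size (default 2000).
#' @param overlap fraction of the universe in the shared core present on every
#'   platform (default 0.8); non-core genes are kept per platform with
#'   probability 0.5. Signal, age, sex and background genes live in the core.
#' @param n_signal planted signal genes (default 150); `effect_size` d in log2
#'   units (default 0.8) with a random +/-1 direction per gene.
#' @param n_background background genes (default 300) at floor `mu_bg`
#'   (default 4) with per-gene sd `sd_bg` (default 0.1).
#' @param mu_expr_mean,mu_expr_sd baseline mean/sd of expressed-gene means
#'   (defaults 8 and 1).
#' @param n_batches batches per cohort (default 2); `batch_sd` tau (default
#'   0.5); `batch_class_cor` rho in \[0,1\] (scalar or per-cohort; default 0).
#' @param age_range control age range in years (default 55-85);
#'   `case_age_shift` years added to case (and half to MCI) ages (default 4);
#'   `n_age_genes` genes with age slope `age_slope` per decade, random sign
#'   (defaults 50 and 0.3).
#' @param n_sex_genes,sex_effect sex-affected genes and their log2 shift in
#'   males (defaults 20 and 0.5).
#' @param mci_mixing pi: probability an MCI sample carries the case signal
#'   (default 0.3).
#' @param noise_sd residual sd sigma (default 1).
#' @param effect_size planted effect d in log2 units (default 0.8).
#' @param seed master seed; every stage seed derives from it.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(n_cohorts = 2L, n_cases = 60L, n_controls = 60L,
                       n_mci = 0L, g_total = 2000L, overlap = 0.8,
                       n_signal = 150L, effect_size = 0.8,
                       n_background = 300L, mu_bg = 4, sd_bg = 0.1,
                       mu_expr_mean = 8, mu_expr_sd = 1,
                       n_batches = 2L, batch_sd = 0.5, batch_class_cor = 0,
                       age_range = c(55, 85), case_age_shift = 4,
                       n_age_genes = 50L, age_slope = 0.3,
                       n_sex_genes = 20L, sex_effect = 0.5,
                       mci_mixing = 0.3, noise_sd = 1, seed = 1L) {
  assert_scalar_number(n_cohorts, "n_cohorts", 1)
  assert_scalar_number(g_total, "g_total", 2)
  assert_scalar_number(overlap, "overlap", 0, 1)
  assert_scalar_number(n_signal, "n_signal", 1)
  assert_scalar_number(n_background, "n_background", 0)
  assert_scalar_number(mci_mixing, "mci_mixing", 0, 1)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(batch_sd, "batch_sd", 0)
  assert_scalar_number(sd_bg, "sd_bg", 0)
  assert_scalar_number(case_age_shift, "case_age_shift", 0)
  if (any(batch_class_cor < 0 | batch_class_cor > 1)) {
    stopf("batch_class_cor must lie in [0, 1]")
  }
  if (n_signal + n_background > g_total) {
    stopf("n_signal + n_background exceeds g_total")
  }
  core_size <- round(overlap * g_total)
  n_struct <- n_signal + n_age_genes + n_sex_genes + n_background
  if (n_struct > core_size) {
    stopf("structured genes (%d) exceed the shared core (%d = overlap * g_total); raise overlap or g_total",
          n_struct, core_size)
  }
  rec <- function(x) rep_len(x, n_cohorts)
  structure(list(
    n_cohorts = as.integer(n_cohorts), n_cases = as.integer(rec(n_cases)),
    n_controls = as.integer(rec(n_controls)), n_mci = as.integer(rec(n_mci)),
    g_total = as.integer(g_total), overlap = overlap,
    n_signal = as.integer(n_signal), effect_size = effect_size,
    n_background = as.integer(n_background), mu_bg = mu_bg, sd_bg = sd_bg,
    mu_expr_mean = mu_expr_mean, mu_expr_sd = mu_expr_sd,
    n_batches = as.integer(rec(n_batches)), batch_sd = batch_sd,
    batch_class_cor = rec(batch_class_cor),
    age_range = age_range, case_age_shift = case_age_shift,
    n_age_genes = as.integer(n_age_genes), age_slope = age_slope,
    n_sex_genes = as.integer(n_sex_genes), sex_effect = sex_effect,
    mci_mixing = mci_mixing, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "SimConfig")
}

#' Gene table underlying a simulation
#'
#' Deterministic given the config seed; [generate_cohorts()] uses exactly this
#' table, so ground-truth roles (signal, age, sex, background) and directions
#' are available for parameter-recovery tests without regenerating data.
#'
#' @param config a [sim_config()].
#' @return data.frame: gene_id, role (`signal`/`age`/`sex`/`expressed`/
#'   `background`), mu, direction (+/-1 for signal genes else 0), age_slope,
#'   sex_effect, core (logical: on every platform).
#' @export
sim_gene_table <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  G <- config$g_total
  ids <- sprintf("g%05d", seq_len(G))
  n_other <- G - config$n_signal - config$n_age_genes - config$n_sex_genes -
    config$n_background
  role <- c(rep("signal", config$n_signal), rep("age", config$n_age_genes),
            rep("sex", config$n_sex_genes), rep("expressed", n_other),
            rep("background", config$n_background))
  with_seed(derive_seed(config$seed, "genes"), {
    mu <- ifelse(role == "background",
                 stats::rnorm(G, config$mu_bg, config$sd_bg),
                 stats::rnorm(G, config$mu_expr_mean, config$mu_expr_sd))
    direction <- ifelse(role == "signal", sample(c(-1L, 1L), G, replace = TRUE), 0L)
    age_slope <- ifelse(role == "age",
                        config$age_slope * sample(c(-1, 1), G, replace = TRUE), 0)
    sex_effect <- ifelse(role == "sex",
                         config$sex_effect * sample(c(-1, 1), G, replace = TRUE), 0)
    # shared core: all structured genes plus the first expressed genes up to
    # round(overlap * G); remaining expressed genes differ between platforms
    core_size <- round(config$overlap * G)
    core <- role != "expressed"
    filler <- which(role == "expressed")[seq_len(max(0L, core_size - sum(core)))]
    core[filler] <- TRUE
    data.frame(gene_id = ids, role = role, mu = mu, direction = direction,
               age_slope = age_slope, sex_effect = sex_effect, core = core,
               stringsAsFactors = FALSE)
  })
}

#' Planted signature (simulation ground truth)
#'
#' @param config a [sim_config()].
#' @return a [directional_signature()] of the planted signal genes with their
#'   true directions.
#' @export
planted_signature <- function(config) {
  genes <- sim_gene_table(config)
  sig <- genes[genes$role == "signal", ]
  directional_signature("planted", sig$gene_id, sig$direction)
}

#' Generate synthetic expression cohorts
#'
#' @param config a [sim_config()].
#' @return list of length `n_cohorts`; each element has `cohort`
#'   ([expression_cohort()], genes restricted to that cohort's platform) and
#'   `metadata` (data.frame with sample_id, cohort_id, age, sex, diagnosis,
#'   batch). Fully reproducible from the config seed.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genes <- sim_gene_table(config)
  lapply(seq_len(config$n_cohorts), function(ci) {
    generate_one_cohort(config, genes, ci)
  })
}

generate_one_cohort <- function(config, genes, ci) {
  cohort_id <- paste0("cohort", ci)
  n1 <- config$n_cases[ci]; n0 <- config$n_controls[ci]; nm <- config$n_mci[ci]
  n <- n1 + n0 + nm
  with_seed(derive_seed(config$seed, cohort_id), {
    # platform universe: core genes plus a per-cohort half of the non-core
    keep <- genes$core | (stats::runif(nrow(genes)) < 0.5)
    gt <- genes[keep, , drop = FALSE]
    diagnosis <- c(rep("AD", n1), rep("MCI", nm), rep("CTL", n0))
    sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))
    lo <- config$age_range[1L]; hi <- config$age_range[2L]
    shift <- ifelse(diagnosis == "AD", config$case_age_shift,
                    ifelse(diagnosis == "MCI", config$case_age_shift / 2, 0))
    age <- round(stats::runif(n, lo, hi) + shift, 1)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    signal <- ifelse(diagnosis == "AD", 1,
                     ifelse(diagnosis == "MCI",
                            stats::rbinom(n, 1L, config$mci_mixing), 0))
    # batch assignment: everyone uniform, then a fraction rho of cases
    # concentrated into batch 1
    K <- config$n_batches[ci]
    batch <- sample.int(K, n, replace = TRUE)
    rho <- config$batch_class_cor[ci]
    if (rho > 0 && K > 1L) {
      case_idx <- which(diagnosis == "AD")
      forced <- sample(case_idx, round(rho * length(case_idx)))
      batch[forced] <- 1L
    }
    G <- nrow(gt)
    bg <- gt$role == "background"
    b_eff <- matrix(stats::rnorm(G * K, 0, config$batch_sd), nrow = G)
    y <- matrix(stats::rnorm(G * n, 0, config$noise_sd), nrow = G,
                dimnames = list(gt$gene_id, sample_ids))
    y <- y + gt$mu + b_eff[, batch, drop = FALSE]
    expr_rows <- !bg
    age_c <- (age - mean(age)) / 10
    male <- as.numeric(sex == "M")
    y[expr_rows, ] <- y[expr_rows, ] +
      config$effect_size * (gt$direction[expr_rows] %o% signal) +
      gt$age_slope[expr_rows] %o% age_c +
      gt$sex_effect[expr_rows] %o% male
    metadata <- data.frame(sample_id = sample_ids, cohort_id = cohort_id,
                           age = age, sex = sex, diagnosis = diagnosis,
                           batch = paste0("b", batch), stringsAsFactors = FALSE)
    list(cohort = expression_cohort(y, cohort_id, platform_id = paste0("platform", ci)),
         metadata = metadata)
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits, in the package's exchange formats: one expression TSV per cohort, a
#' combined metadata TSV, the planted signature TSV, an exclusion list of the
#' planted gene ids (for filtered-pool experiments), a GMT of the planted set
#' plus random decoy sets, and a manifest JSON recording the config, seed and
#' an md5 checksum per file.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_decoy_sets random decoy gene-sets in the GMT (default 3).
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
write_fixture_bundle <- function(config, out_dir, n_decoy_sets = 3L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sims <- generate_cohorts(config)
  genes <- sim_gene_table(config)
  files <- character()
  for (s in sims) {
    f <- file.path(out_dir, paste0(s$cohort$cohort_id, "_expression.tsv"))
    write_expression_cohort(s$cohort, f)
    files <- c(files, f)
  }
  md <- do.call(rbind, lapply(sims, `[[`, "metadata"))
  f <- file.path(out_dir, "metadata.tsv")
  write_sample_metadata(md, f); files <- c(files, f)
  sig <- planted_signature(config)
  f <- file.path(out_dir, "planted_signature.tsv")
  write_signature(sig, f); files <- c(files, f)
  f <- file.path(out_dir, "exclusion_planted.txt")
  writeLines(c("# planted signal genes (simulation ground truth)", sig$gene_ids), f)
  files <- c(files, f)
  expressed <- genes$gene_id[genes$role != "background"]
  decoys <- with_seed(derive_seed(config$seed, "decoys"), {
    lapply(seq_len(n_decoy_sets), function(i) sample(expressed, length(sig$gene_ids)))
  })
  sets <- c(list(planted = sig$gene_ids),
            stats::setNames(decoys, paste0("decoy", seq_len(n_decoy_sets))))
  f <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(sets, f, descriptions = c("planted signal genes",
                                      rep("random decoy set", n_decoy_sets)))
  files <- c(files, f)
  manifest <- list(
    config = unclass(config), seed = config$seed,
    files = lapply(files, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
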