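# End-to-end benchmark orchestration: load or simulate cohorts, select
# clinical groups, optionally match, evaluate the candidate and random-set
# nulls under each requested scheme/pool, attach significance and the
# design-criteria checklist.

#' Run a full signature benchmark from a config
#'
#' The config (a named list, or a path to a YAML file) describes one
#' benchmark run:
#' \preformatted{
#' run_id: demo
#' seed: 42                     # master seed; every stage seed derives from it
#' sim: {n_cohorts: 2, effect_size: 0.8, ...}   # OR inputs: see below
#' candidate: planted           # "planted" (sim only) or a signature TSV path
#' case_definitions: [AD_vs_CTL]             # and/or ADMCI_vs_CTL
#' arms: [unmatched]                         # and/or matched
#' matching: {age_tolerance: 5}
#' schemes:
#'   - {name: within75, mode: within, split_fraction: 0.75, n_repeats: 10,
#'      cohort: cohort1}
#'   - {name: cross12, mode: cross, train_cohort_id: cohort1,
#'      test_cohort_ids: [cohort2]}
#' pools:
#'   - {name: all1, type: all, cohort: cohort1}
#'   - {name: bg1, type: background, cohort: cohort1, floor_quantile: 0.25,
#'      sample_fraction: 0.8}
#'   - {name: flt1, type: filtered, cohort: cohort1, exclusion: planted}
#' null: {set_size: 150, n_sets: 200}
#' alpha: 0.05
#' }
#' With real inputs instead of `sim`:
#' \preformatted{
#' inputs:
#'   cohorts:
#'     - {path: cohort1.tsv, cohort_id: cohort1, platform_id: p1}
#'   metadata: metadata.tsv
#' }
#' One report cell is produced per (scheme, case definition, arm, pool):
#' candidate validation result, null distribution summary, empirical p and
#' rank, per-test-cohort Mann-Whitney p for cross schemes, and BH-adjusted
#' empirical p across the cells. All randomness derives from the master seed,
#' so a rerun with the same config is bit-identical.
#'
#' @param config named list or YAML path.
#' @param out_dir optional output directory; when given, the report and all
#'   cell tables are written there (deterministic content, no timestamps) via
#'   [write_benchmark_report()].
#' @return an object of class `BenchmarkReport`.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "config"
  report <- tryCatch({
    cfg <- validate_run_config(config)
    master <- cfg$seed

    stage <- "load"
    data <- load_benchmark_data(cfg, master)

    stage <- "candidate"
    candidate <- resolve_candidate(cfg, data)

    stage <- "evaluate"
    cells <- build_cells(cfg, data, candidate, master)

    stage <- "significance"
    emp <- vapply(cells, function(cl) cl$significance$empirical_p, 0)
    adj <- bh_adjust(emp)
    for (i in seq_along(cells)) cells[[i]]$significance$bh_adjusted_p <- adj[i]

    stage <- "checklist"
    checklist <- build_checklist(cells)

    structure(list(run_id = cfg$run_id, config = cfg, cells = cells,
                   checklist = checklist,
                   provenance = list(master_seed = master,
                                     package_version = as.character(utils::packageVersion("sigbench")))),
              class = "BenchmarkReport")
  }, error = function(e) {
    stopf("benchmark failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(out_dir)) write_benchmark_report(report, out_dir)
  report
}

validate_run_config <- function(config) {
  if (is.null(config$seed)) stopf("config requires a master 'seed'")
  if (is.null(config$sim) && is.null(config$inputs)) {
    stopf("config requires either a 'sim' block or an 'inputs' block")
  }
  if (is.null(config$candidate)) stopf("config requires a 'candidate' (signature path or 'planted')")
  if (is.null(config$schemes) || !length(config$schemes)) stopf("config requires at least one scheme")
  if (is.null(config$pools) || !length(config$pools)) stopf("config requires at least one pool")
  config$run_id <- config$run_id %||% "run"
  config$case_definitions <- config$case_definitions %||% "AD_vs_CTL"
  config$arms <- config$arms %||% "unmatched"
  if (!all(config$arms %in% c("unmatched", "matched"))) {
    stopf("arms must be drawn from {unmatched, matched}")
  }
  config$alpha <- config$alpha %||% 0.05
  config$matching <- config$matching %||% list()
  config$matching$age_tolerance <- config$matching$age_tolerance %||% 5
  config$null <- config$null %||% list()
  config$null$set_size <- config$null$set_size %||% 150L
  config$null$n_sets <- config$null$n_sets %||% 1000L
  config$seed <- as.integer(config$seed)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_benchmark_data <- function(cfg, master) {
  if (!is.null(cfg$sim)) {
    sim_args <- cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(master, "sim")
    if (!is.null(sim_args$age_range)) sim_args$age_range <- unlist(sim_args$age_range)
    simc <- do.call(sim_config, sim_args)
    sims <- generate_cohorts(simc)
    cohorts <- stats::setNames(lapply(sims, `[[`, "cohort"),
                               vapply(sims, function(s) s$cohort$cohort_id, ""))
    metadata <- do.call(rbind, lapply(sims, `[[`, "metadata"))
    list(cohorts = cohorts, metadata = metadata, sim = simc)
  } else {
    specs <- cfg$inputs$cohorts
    cohorts <- stats::setNames(
      lapply(specs, function(s) {
        read_expression_cohort(s$path, s$cohort_id, s$platform_id %||% s$cohort_id)
      }),
      vapply(specs, function(s) s$cohort_id, ""))
    metadata <- read_sample_metadata(cfg$inputs$metadata)
    list(cohorts = cohorts, metadata = metadata, sim = NULL)
  }
}

resolve_candidate <- function(cfg, data) {
  if (identical(cfg$candidate, "planted")) {
    if (is.null(data$sim)) stopf("candidate 'planted' requires a sim block")
    planted_signature(data$sim)
  } else {
    read_signature(cfg$candidate)
  }
}

# labels per cohort for one (case_definition, arm)
cell_labels <- function(cfg, data, case_def, arm, master) {
  lapply(stats::setNames(nm = names(data$cohorts)), function(cid) {
    md <- data$metadata[data$metadata$cohort_id == cid, , drop = FALSE]
    labels <- select_diagnosis_groups(md, case_def)
    if (arm == "matched") {
      m <- match_cases_controls(md, labels,
                                age_tolerance = cfg$matching$age_tolerance,
                                seed = derive_seed(master, paste0("match:", case_def, ":", cid)))
      labels <- m$labels
    }
    labels
  })
}

build_pool <- function(pcfg, data) {
  cohort <- data$cohorts[[pcfg$cohort %||% names(data$cohorts)[1L]]]
  if (is.null(cohort)) stopf("pool '%s': unknown cohort", pcfg$name)
  pool <- switch(pcfg$type,
    all = all_genes_pool(cohort),
    background = background_pool(cohort,
                                 floor_quantile = pcfg$floor_quantile %||% 0.25,
                                 sample_fraction = pcfg$sample_fraction %||% 0.8),
    filtered = {
      excl <- if (identical(pcfg$exclusion, "planted")) {
        if (is.null(data$sim)) stopf("pool '%s': exclusion 'planted' requires a sim block", pcfg$name)
        planted_signature(data$sim)$gene_ids
      } else {
        read_exclusion_list(pcfg$exclusion)
      }
      filtered_pool(all_genes_pool(cohort), excl)
    },
    stopf("pool '%s': unknown type '%s'", pcfg$name, pcfg$type))
  pool$name <- pcfg$name
  pool
}

build_scheme <- function(scfg, master) {
  scheme_config(mode = scfg$mode,
                split_fraction = scfg$split_fraction %||% 0.75,
                n_repeats = scfg$n_repeats %||% 10L,
                train_cohort_id = scfg$train_cohort_id,
                test_cohort_ids = unlist(scfg$test_cohort_ids),
                seed = derive_seed(master, paste0("scheme:", scfg$name)))
}

build_cells <- function(cfg, data, candidate, master) {
  pools <- lapply(cfg$pools, build_pool, data = data)
  names(pools) <- vapply(cfg$pools, `[[`, "", "name")
  cells <- list()
  for (scfg in cfg$schemes) {
    scheme <- build_scheme(scfg, master)
    within_cohort <- scfg$cohort %||% names(data$cohorts)[1L]
    for (case_def in cfg$case_definitions) {
      for (arm in cfg$arms) {
        labels_by_cohort <- cell_labels(cfg, data, case_def, arm, master)
        if (scheme$mode == "within") {
          cohort <- data$cohorts[[within_cohort]]
          labels <- labels_by_cohort[[within_cohort]]
          cand <- within_cohort_cv(cohort, labels, candidate, scheme,
                                   set_name = candidate$name)
          parametric <- NULL
        } else {
          cand <- cross_cohort_validate(data$cohorts, labels_by_cohort,
                                        candidate, scheme, set_name = candidate$name)
          parametric <- candidate_parametric(data, labels_by_cohort, candidate, scheme)
        }
        for (pname in names(pools)) {
          key <- paste(scfg$name, case_def, arm, pname, sep = "|")
          samp <- sampling_config(pools[[pname]], set_size = cfg$null$set_size,
                                  n_sets = cfg$null$n_sets,
                                  seed = derive_seed(master, paste0("null:", key)))
          sets <- sample_gene_sets(samp)
          null <- if (scheme$mode == "within") {
            evaluate_null(sets, data$cohorts[[within_cohort]],
                          labels_by_cohort[[within_cohort]], scheme, config = samp)
          } else {
            evaluate_null(sets, data$cohorts, labels_by_cohort, scheme, config = samp)
          }
          sig <- significance_result(cand$mean_auc, null,
                                     parametric_p = if (!is.null(parametric)) max(parametric$p) else NA_real_,
                                     replicated_all_cohorts = if (!is.null(parametric)) parametric$replicated else NA)
          cells[[key]] <- list(
            scheme_name = scfg$name, scheme_mode = scheme$mode,
            case_definition = case_def, arm = arm, pool = pname,
            candidate = cand, candidate_units = validation_result_table(cand),
            parametric = parametric,
            null = null, null_summary = null_summary(null),
            significance = sig, alpha = cfg$alpha)
        }
      }
    }
  }
  cells
}

# per-test-cohort Mann-Whitney significance of the candidate's scores under a
# cross scheme, plus the all-cohorts replication verdict
candidate_parametric <- function(data, labels_by_cohort, candidate, scheme) {
  ctx <- cross_context(data$cohorts, labels_by_cohort, scheme)
  fit_genes <- intersect(candidate$gene_ids, names(ctx$train_diff))
  dirs <- ifelse(ctx$train_diff[fit_genes] >= 0, 1L, -1L)
  p <- vapply(ctx$tests, function(ts) {
    g <- fit_genes[fit_genes %in% ts$cohort$gene_ids]
    d <- dirs[fit_genes %in% ts$cohort$gene_ids]
    scores <- score_from_ranks(ts$ranks, g[d == 1L], g[d == -1L], nrow(ts$ranks))
    auc_parametric_p(scores, ts$labels)$p
  }, 0)
  verdict <- if (length(p) >= 2L) replication_verdict(p, alpha = 0.05)$replicated else p[[1L]] < 0.05
  list(p = p, replicated = verdict)
}

build_checklist <- function(cells) {
  modes <- vapply(cells, `[[`, "", "scheme_mode")
  cross <- cells[modes == "cross"]
  list(
    external_validation_done = any(modes == "cross"),
    significant_in_all_test_cohorts =
      length(cross) > 0 && any(vapply(cross, function(cl) {
        isTRUE(cl$significance$replicated_all_cohorts)
      }, TRUE)),
    matched_design_used = any(vapply(cells, `[[`, "", "arm") == "matched"),
    mci_excluded = any(vapply(cells, `[[`, "", "case_definition") == "AD_vs_CTL"),
    multiple_testing_corrected =
      all(vapply(cells, function(cl) is.finite(cl$significance$bh_adjusted_p), TRUE))
  )
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf("BenchmarkReport '%s': %d cell(s)\n", x$run_id, length(x$cells)))
  print(benchmark_cell_table(x))
  invisible(x)
}

#' Flat per-cell summary of a benchmark report
#' @param report a `BenchmarkReport`.
#' @return data.frame, one row per cell.
#' @export
benchmark_cell_table <- function(report) {
  do.call(rbind, lapply(names(report$cells), function(key) {
    cl <- report$cells[[key]]
    data.frame(cell = key, scheme = cl$scheme_name, mode = cl$scheme_mode,
               case_definition = cl$case_definition, arm = cl$arm, pool = cl$pool,
               candidate_auc = cl$candidate$mean_auc,
               null_mean = cl$null_summary$mean, null_p95 = cl$null_summary$p95,
               rank = cl$significance$rank, empirical_p = cl$significance$empirical_p,
               bh_p = cl$significance$bh_adjusted_p,
               parametric_p = cl$significance$parametric_p,
               n_null = length(cl$null$aucs), n_failed = cl$null$n_failed,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write a benchmark report directory
#'
#' Deterministic content for fixed config and seeds: `report.json` (cells,
#' checklist, provenance), `cells.tsv`, and one `null_<cell>.tsv` (+ JSON
#' sidecar) per cell. No timestamps are embedded, so two runs with the same
#' config produce byte-identical files.
#'
#' @param report a `BenchmarkReport`.
#' @param out_dir output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark_report <- function(report, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stopf("output directory '%s' exists and is not empty (reports are append-only)", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  tab <- benchmark_cell_table(report)
  utils::write.table(tab, file.path(out_dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (key in names(report$cells)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    write_null_distribution(report$cells[[key]]$null,
                            file.path(out_dir, paste0("null_", safe, ".tsv")))
  }
  json_cells <- lapply(report$cells, function(cl) {
    list(scheme = cl$scheme_name, mode = cl$scheme_mode,
         case_definition = cl$case_definition, arm = cl$arm, pool = cl$pool,
         candidate_auc = cl$candidate$mean_auc,
         candidate_units = cl$candidate_units,
         null_summary = cl$null_summary,
         significance = unclass(cl$significance))
  })
  jsonlite::write_json(
    list(run_id = report$run_id, checklist = report$checklist,
         provenance = report$provenance, cells = json_cells),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  ok <- TRUE
  invisible(out_dir)
}

#' Compare two arms of a benchmark report
#'
#' An "arm" is any single value of one cell component — a scheme name (e.g.
#' split 0.5 vs 0.75), a case definition (AD_vs_CTL vs ADMCI_vs_CTL), a
#' matching arm, or a pool. Cells are paired across the two arm values with
#' all other components equal, and per-pair differences of candidate AUC,
#' null mean AUC, and the candidate-minus-null-mean margin are tabulated
#' (arm_a minus arm_b).
#'
#' @param report a `BenchmarkReport`.
#' @param arm_a,arm_b component values to compare.
#' @return data.frame of per-pair deltas.
#' @export
compare_arms <- function(report, arm_a, arm_b) {
  fields <- c("scheme_name", "case_definition", "arm", "pool")
  comp <- function(cl) vapply(fields, function(f) cl[[f]], "")
  comps <- lapply(report$cells, comp)
  field_of <- function(v) {
    hit <- unique(unlist(lapply(comps, function(x) names(x)[x == v])))
    if (!length(hit)) stopf("arm '%s' matches no cell in the report", v)
    if (length(hit) > 1L) stopf("arm '%s' is ambiguous across components: %s",
                                v, paste(hit, collapse = ", "))
    hit
  }
  fa <- field_of(arm_a); fb <- field_of(arm_b)
  if (fa != fb) stopf("arms '%s' and '%s' belong to different components (%s vs %s)",
                      arm_a, arm_b, fa, fb)
  a_cells <- report$cells[vapply(comps, function(x) x[[fa]] == arm_a, TRUE)]
  rows <- lapply(names(a_cells), function(key_a) {
    ca <- comp(a_cells[[key_a]]); ca[[fa]] <- arm_b
    key_b <- names(report$cells)[vapply(comps, identical, TRUE, y = ca)]
    if (!length(key_b)) return(NULL)
    cla <- a_cells[[key_a]]; clb <- report$cells[[key_b[[1L]]]]
    ma <- cla$candidate$mean_auc - cla$null_summary$mean
    mb <- clb$candidate$mean_auc - clb$null_summary$mean
    data.frame(cell_a = key_a, cell_b = key_b[[1L]],
               candidate_auc_a = cla$candidate$mean_auc,
               candidate_auc_b = clb$candidate$mean_auc,
               d_candidate_auc = cla$candidate$mean_auc - clb$candidate$mean_auc,
               null_mean_a = cla$null_summary$mean,
               null_mean_b = clb$null_summary$mean,
               d_null_mean = cla$null_summary$mean - clb$null_summary$mean,
               margin_a = ma, margin_b = mb, d_margin = ma - mb,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stopf("no comparable cell pairs between '%s' and '%s'", arm_a, arm_b)
  do.call(rbind, rows)
}

#' Export a plot-ready null-vs-candidate table for one cell
#'
#' One row per null AUC (flag `is_candidate` = 0) plus the flagged candidate
#' row — the datum plotted as the highlighted dot against a null histogram.
#'
#' @param report a `BenchmarkReport`.
#' @param cell cell key (see [benchmark_cell_table()]).
#' @param path optional TSV output path.
#' @return the data.frame, invisibly if written.
#' @export
export_figure_table <- function(report, cell, path = NULL) {
  cl <- report$cells[[cell]]
  if (is.null(cl)) stopf("cell '%s' not present in the report", cell)
  df <- data.frame(
    gene_set = c(paste0("null_", seq_along(cl$null$aucs)), cl$candidate$gene_set_name),
    auc = c(cl$null$aucs, cl$candidate$mean_auc),
    is_candidate = c(rep(0L, length(cl$null$aucs)), 1L),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
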