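# Random gene-set sampling and empirical null AUC distributions.

#' Random gene-set sampling configuration
#'
#' @param pool a [gene_pool()] to sample from.
#' @param set_size genes per set, drawn without replacement within a set
#'   (default 150, the size of the benchmarked signature).
#' @param n_sets number of independent sets; a gene may recur across sets.
#' @param seed integer seed.
#' @return an object of class `SamplingConfig`.
#' @export
sampling_config <- function(pool, set_size = 150L, n_sets, seed = 1L) {
  stopifnot(inherits(pool, "GenePool"))
  assert_scalar_number(set_size, "set_size", 1)
  assert_scalar_number(n_sets, "n_sets", 1)
  if (set_size > length(pool$gene_ids)) {
    stopf("set_size (%d) exceeds pool '%s' size (%d)",
          as.integer(set_size), pool$name, length(pool$gene_ids))
  }
  structure(list(pool = pool, set_size = as.integer(set_size),
                 n_sets = as.integer(n_sets), seed = as.integer(seed)),
            class = "SamplingConfig")
}

#' Draw random gene-sets from a pool
#'
#' Each set is a uniform draw of `set_size` distinct genes from the pool;
#' sets are drawn independently of one another. When two platforms with
#' different gene content are benchmarked, either keep one sampling object
#' per platform pool (independent per-platform nulls) or sample from
#' [intersect_pools()] so the same set is evaluable on both (paired mode).
#'
#' @param config a [sampling_config()].
#' @return list of character vectors of gene ids, length `n_sets`.
#' @export
sample_gene_sets <- function(config) {
  stopifnot(inherits(config, "SamplingConfig"))
  pool <- config$pool$gene_ids
  with_seed(config$seed, {
    lapply(seq_len(config$n_sets), function(i) sample(pool, config$set_size))
  })
}

#' Evaluate random gene-sets to form an empirical null AUC distribution
#'
#' Every set is run through the stated validation scheme
#' ([within_cohort_cv()] or [cross_cohort_validate()]) and its mean AUC
#' recorded. Per-set failures (e.g. a set with no genes on a test platform)
#' are recorded and excluded from the distribution, never silently dropped:
#' `n_failed` is part of the distribution's provenance. Rank matrices and
#' splits are computed once per scheme, so results are bit-identical to
#' evaluating each set individually, only faster.
#'
#' @param sets list of gene-id vectors (see [sample_gene_sets()]).
#' @param cohorts a single [expression_cohort()] (within mode) or a named
#'   list of cohorts (cross mode).
#' @param labels a named logical label vector (within mode) or a named list
#'   of label vectors per cohort id (cross mode).
#' @param scheme a [scheme_config()].
#' @param config optional [sampling_config()] echoed into the result.
#' @return an object of class `NullDistribution`: `aucs` (length = number of
#'   successfully evaluated sets), `n_sets`, `n_failed`, `failed_idx`,
#'   `failures` (messages), `scheme`, `config`.
#' @export
evaluate_null <- function(sets, cohorts, labels, scheme, config = NULL) {
  stopifnot(inherits(scheme, "SchemeConfig"))
  if (!length(sets)) stopf("no gene sets supplied")
  sets <- lapply(sets, as_gene_ids)
  if (scheme$mode == "within") {
    cohort <- if (inherits(cohorts, "ExpressionCohort")) cohorts else cohorts[[1L]]
    ctx <- within_context(cohort, labels, scheme)
    per_set <- eval_sets_within(ctx, sets)
  } else {
    ctx <- cross_context(cohorts, labels, scheme)
    per_set <- eval_sets_cross(ctx, sets)
  }
  failed <- vapply(per_set, inherits, TRUE, what = "condition")
  aucs <- vapply(per_set[!failed], function(units) {
    mean(vapply(units, function(a) a$auc, 0))
  }, 0)
  if (any(failed)) {
    message(sprintf("evaluate_null: %d/%d set(s) failed and were excluded",
                    sum(failed), length(sets)))
  }
  structure(list(aucs = aucs, n_sets = length(sets), n_failed = sum(failed),
                 failed_idx = which(failed),
                 failures = vapply(per_set[failed], conditionMessage, ""),
                 scheme = scheme, config = config),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: %d AUC values (%d of %d sets failed), mean %.4f\n",
              length(x$aucs), x$n_failed, x$n_sets, mean(x$aucs)))
  invisible(x)
}

#' Summarise a null AUC distribution
#'
#' @param null a `NullDistribution` or bare numeric vector of AUCs.
#' @return list with `n`, `mean`, `sd`, `min`, `max` and percentiles
#'   `p50`, `p90`, `p95`, `p99`, `p100`.
#' @export
null_summary <- function(null) {
  aucs <- if (inherits(null, "NullDistribution")) null$aucs else as.numeric(null)
  if (!length(aucs)) stopf("null distribution is empty")
  q <- stats::quantile(aucs, probs = c(0.5, 0.9, 0.95, 0.99, 1), names = FALSE)
  list(n = length(aucs), mean = mean(aucs), sd = stats::sd(aucs),
       min = min(aucs), max = max(aucs),
       p50 = q[1L], p90 = q[2L], p95 = q[3L], p99 = q[4L], p100 = q[5L])
}

#' Write a null distribution as TSV plus a JSON provenance sidecar
#'
#' @param null a `NullDistribution`.
#' @param path output TSV path (`<path>.json` gets the sidecar).
#' @export
write_null_distribution <- function(null, path) {
  ok_idx <- setdiff(seq_len(null$n_sets), null$failed_idx)
  df <- data.frame(set_index = c(ok_idx, null$failed_idx),
                   mean_auc = c(null$aucs, rep(NA_real_, null$n_failed)),
                   failed = c(rep(0L, length(null$aucs)), rep(1L, null$n_failed)))
  df <- df[order(df$set_index), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(n_sets = null$n_sets, n_failed = null$n_failed,
               scheme = unclass(null$scheme),
               sampling = if (!is.null(null$config)) {
                 list(pool = null$config$pool$name,
                      pool_provenance = null$config$pool$provenance,
                      platform = null$config$pool$platform_id,
                      set_size = null$config$set_size,
                      n_sets = null$config$n_sets,
                      seed = null$config$seed)
               })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
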