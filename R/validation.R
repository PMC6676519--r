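# Validation schemes: within-cohort repeated splits and cross-cohort external
# validation; clinical group selection and age/sex case-control matching.

#' Validation scheme configuration
#'
#' `within` mode repeats stratified train/test splits inside one cohort:
#' directions are fitted on the training share and AUC measured on the
#' held-out share. `cross` mode fits directions once on an entire training
#' cohort and measures AUC on fully independent test cohorts — the external
#' "gold standard". 0.5 and 0.75 are the two named training-share presets; any
#' fraction in (0,1) is accepted.
#'
#' @param mode `"within"` or `"cross"`.
#' @param split_fraction training share for within mode (default 0.75).
#' @param n_repeats number of repeated splits for within mode (default 10).
#' @param train_cohort_id,test_cohort_ids cohort ids for cross mode; the train
#'   cohort must be distinct from every test cohort.
#' @param seed integer seed controlling the split draws.
#' @return an object of class `SchemeConfig`.
#' @export
scheme_config <- function(mode = c("within", "cross"), split_fraction = 0.75,
                          n_repeats = 10L, train_cohort_id = NULL,
                          test_cohort_ids = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "within") {
    assert_scalar_number(split_fraction, "split_fraction", 0, 1,
                         strict_lower = TRUE, strict_upper = TRUE)
    assert_scalar_number(n_repeats, "n_repeats", 1)
  } else {
    if (is.null(train_cohort_id) || is.null(test_cohort_ids) || !length(test_cohort_ids)) {
      stopf("cross mode requires train_cohort_id and at least one test cohort id")
    }
    if (train_cohort_id %in% test_cohort_ids) {
      stopf("train cohort '%s' cannot also be a test cohort", train_cohort_id)
    }
  }
  structure(list(mode = mode,
                 split_fraction = if (mode == "within") split_fraction else NULL,
                 n_repeats = if (mode == "within") as.integer(n_repeats) else NULL,
                 train_cohort_id = train_cohort_id,
                 test_cohort_ids = test_cohort_ids,
                 seed = as.integer(seed)),
            class = "SchemeConfig")
}

#' Select diagnosis groups and assign binary labels
#'
#' `AD_vs_CTL` drops MCI samples entirely and labels AD as cases.
#' `ADMCI_vs_CTL` merges AD with MCI as cases — the clinically heterogeneous
#' design this pipeline exists to measure the cost of, since only a fraction
#' of MCI individuals carry AD biology.
#'
#' @param metadata sample metadata data.frame (see [read_sample_metadata()]).
#' @param case_definition `"AD_vs_CTL"` or `"ADMCI_vs_CTL"`.
#' @return named logical label vector (TRUE = case) over the retained samples.
#' @export
select_diagnosis_groups <- function(metadata, case_definition = c("AD_vs_CTL", "ADMCI_vs_CTL")) {
  case_definition <- match.arg(case_definition)
  keep <- if (case_definition == "AD_vs_CTL") {
    metadata$diagnosis %in% c("AD", "CTL")
  } else {
    metadata$diagnosis %in% c("AD", "MCI", "CTL")
  }
  md <- metadata[keep, , drop = FALSE]
  labels <- md$diagnosis != "CTL"
  names(labels) <- md$sample_id
  if (!any(labels)) stopf("%s: no case samples after selection", case_definition)
  if (!any(!labels)) stopf("%s: no control samples after selection", case_definition)
  labels
}

#' Match cases with controls on age and sex
#'
#' Greedy 1:1 matching within sex strata: cases are visited in descending age
#' and each is paired with the unmatched same-sex control minimising the
#' absolute age difference, accepted only if within `age_tolerance` years.
#' Unmatched cases are dropped (and counted). The seed shuffles control order
#' beforehand so exact-distance ties break reproducibly. Age and sex are the
#' two dominant risk factors for late-life dementia; leaving them unmatched
#' lets demographic signal masquerade as disease signal.
#'
#' @param metadata metadata data.frame restricted to the labelled samples.
#' @param labels named logical label vector (TRUE = case).
#' @param age_tolerance maximum |age difference| in years (default 5).
#' @param seed integer tie-break seed.
#' @return list with `pairs` (data.frame: case_id, control_id, sex, case_age,
#'   control_age, age_diff), `labels` (label vector restricted to matched
#'   samples), `n_unmatched_cases`.
#' @export
match_cases_controls <- function(metadata, labels, age_tolerance = 5, seed = 1L) {
  assert_labels(labels)
  assert_scalar_number(age_tolerance, "age_tolerance", 0)
  md <- metadata[match(names(labels), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stopf("labels reference samples absent from metadata")
  cases <- md[labels, , drop = FALSE]
  controls <- md[!labels, , drop = FALSE]
  controls <- with_seed(seed, controls[sample.int(nrow(controls)), , drop = FALSE])
  cases <- cases[order(-cases$age), , drop = FALSE]
  available <- rep(TRUE, nrow(controls))
  pairs <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    cand <- which(available & controls$sex == cases$sex[i])
    if (!length(cand)) next
    dist <- abs(controls$age[cand] - cases$age[i])
    j <- cand[which.min(dist)]
    if (abs(controls$age[j] - cases$age[i]) <= age_tolerance) {
      available[j] <- FALSE
      pairs[[i]] <- data.frame(case_id = cases$sample_id[i],
                               control_id = controls$sample_id[j],
                               sex = cases$sex[i],
                               case_age = cases$age[i],
                               control_age = controls$age[j],
                               age_diff = abs(cases$age[i] - controls$age[j]),
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stopf("matching produced zero case-control pairs at age_tolerance=%g", age_tolerance)
  }
  matched_ids <- c(pairs$case_id, pairs$control_id)
  list(pairs = pairs,
       labels = labels[names(labels) %in% matched_ids],
       n_unmatched_cases = nrow(cases) - nrow(pairs))
}

# Draw stratified train/test splits for a within-cohort scheme. Returns a list
# of length n_repeats of logical train indicators over `labels`. A split whose
# test share lacks a class is re-drawn (at most 100 attempts).
draw_splits <- function(labels, scheme) {
  n <- length(labels)
  case_idx <- which(labels)
  ctl_idx <- which(!labels)
  n1_train <- round(scheme$split_fraction * length(case_idx))
  n0_train <- round(scheme$split_fraction * length(ctl_idx))
  with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      for (attempt in seq_len(100L)) {
        train <- rep(FALSE, n)
        train[sample(case_idx, n1_train)] <- TRUE
        train[sample(ctl_idx, n0_train)] <- TRUE
        ok <- any(labels & train) && any(!labels & train) &&
          any(labels & !train) && any(!labels & !train)
        if (ok) return(train)
      }
      stopf("could not draw a split with both classes in train and test after 100 attempts")
    })
  })
}

new_validation_result <- function(gene_set_name, scheme, per_unit_auc) {
  structure(list(gene_set_name = gene_set_name, scheme = scheme,
                 per_unit_auc = per_unit_auc,
                 mean_auc = mean(vapply(per_unit_auc, function(a) a$auc, 0))),
            class = "ValidationResult")
}

#' @export
print.ValidationResult <- function(x, ...) {
  cat(sprintf("ValidationResult '%s' (%s): mean AUC %.4f over %d unit(s)\n",
              x$gene_set_name, x$scheme$mode, x$mean_auc, length(x$per_unit_auc)))
  invisible(x)
}

#' Within-cohort repeated split validation
#'
#' For each repeat, a stratified random split assigns `split_fraction` of each
#' class to training; gene directions are fitted on the training samples
#' ([fit_directions()]) and the directional score + AUC are measured on the
#' held-out samples. Fully reproducible from the scheme seed. This is the
#' design prone to optimism whenever batch structure correlates with class:
#' both halves of a split share the cohort's batches.
#'
#' @param cohort an [expression_cohort()].
#' @param labels named logical label vector (TRUE = case) over cohort samples.
#' @param gene_set character vector of gene ids, or a
#'   [directional_signature()] (its genes are used; directions are re-fitted
#'   on each training share so candidate and null sets are treated
#'   identically).
#' @param scheme a [scheme_config()] with mode `"within"`.
#' @param set_name name recorded in the result.
#' @return a `ValidationResult`: per-repeat `AucResult`s and their mean.
#' @export
within_cohort_cv <- function(cohort, labels, gene_set, scheme,
                             set_name = NULL) {
  stopifnot(inherits(scheme, "SchemeConfig"))
  if (scheme$mode != "within") stopf("scheme mode must be 'within'")
  if (is.null(set_name)) set_name <- set_label(gene_set)
  ctx <- within_context(cohort, labels, scheme)
  aucs <- eval_sets_within(ctx, list(as_gene_ids(gene_set)))[[1L]]
  if (inherits(aucs, "condition")) stop(aucs)
  new_validation_result(set_name, scheme, aucs)
}

# Precompute everything shared across gene-sets for a within-cohort scheme:
# rank matrix, splits, per-split mean-difference vectors (for direction
# fitting) restricted to the labelled samples.
within_context <- function(cohort, labels, scheme) {
  assert_labels(labels)
  if (!all(names(labels) %in% cohort$sample_ids)) {
    stopf("labels reference samples absent from cohort '%s'", cohort$cohort_id)
  }
  sub <- expression_cohort(cohort$values[, names(labels), drop = FALSE],
                           cohort$cohort_id, cohort$platform_id)
  R <- sample_ranks(sub)
  splits <- draw_splits(labels, scheme)
  per_split <- lapply(splits, function(train) {
    X <- sub$values
    diff <- rowMeans(X[, train & labels, drop = FALSE]) -
      rowMeans(X[, train & !labels, drop = FALSE])
    list(train = train, diff = diff)
  })
  list(cohort = sub, labels = labels, ranks = R, per_split = per_split)
}

# Evaluate a list of gene-sets under a prepared within-cohort context.
# Returns, per set, a list of per-repeat AucResult (or a condition object on
# failure, for the null-evaluation bookkeeping).
eval_sets_within <- function(ctx, sets) {
  G <- nrow(ctx$ranks)
  labels <- ctx$labels
  lapply(sets, function(genes) {
    tryCatch({
      genes <- intersect(genes, ctx$cohort$gene_ids)
      if (!length(genes)) stopf("gene set shares no genes with platform '%s'",
                                ctx$cohort$platform_id)
      lapply(seq_along(ctx$per_split), function(r) {
        sp <- ctx$per_split[[r]]
        dirs <- ifelse(sp$diff[genes] >= 0, 1L, -1L)
        test <- !sp$train
        Rtest <- ctx$ranks[, test, drop = FALSE]
        scores <- score_from_ranks(Rtest, genes[dirs == 1L], genes[dirs == -1L], G)
        auc(scores, labels[test])
      })
    }, error = function(e) e)
  })
}

#' Cross-cohort external validation
#'
#' Directions are fitted once on the entire training cohort — the signature
#' then travels unchanged to each independent test cohort, where per-sample
#' ranks are computed within that cohort and AUC measured. Refitting on test
#' cohorts would reintroduce exactly the leakage external validation exists
#' to rule out. Signature genes absent from a test platform follow the
#' scoring module's intersect-and-warn rule.
#'
#' @param cohorts named list of [expression_cohort()] objects (names are
#'   cohort ids) containing the train cohort and every test cohort.
#' @param labels_by_cohort named list of label vectors, one per cohort id.
#' @param gene_set character vector of gene ids or a [directional_signature()]
#'   (genes used; directions re-fitted on the training cohort).
#' @param scheme a [scheme_config()] with mode `"cross"`.
#' @param set_name name recorded in the result.
#' @return a `ValidationResult`: one `AucResult` per test cohort plus the mean.
#' @export
cross_cohort_validate <- function(cohorts, labels_by_cohort, gene_set, scheme,
                                  set_name = NULL) {
  stopifnot(inherits(scheme, "SchemeConfig"))
  if (scheme$mode != "cross") stopf("scheme mode must be 'cross'")
  if (is.null(set_name)) set_name <- set_label(gene_set)
  ctx <- cross_context(cohorts, labels_by_cohort, scheme)
  aucs <- eval_sets_cross(ctx, list(as_gene_ids(gene_set)))[[1L]]
  if (inherits(aucs, "condition")) stop(aucs)
  new_validation_result(set_name, scheme, aucs)
}

cross_context <- function(cohorts, labels_by_cohort, scheme) {
  need <- c(scheme$train_cohort_id, scheme$test_cohort_ids)
  miss <- setdiff(need, names(cohorts))
  if (length(miss)) stopf("cohort(s) not supplied: %s", paste(miss, collapse = ", "))
  miss <- setdiff(need, names(labels_by_cohort))
  if (length(miss)) stopf("labels not supplied for cohort(s): %s", paste(miss, collapse = ", "))
  train <- cohorts[[scheme$train_cohort_id]]
  train_labels <- assert_labels(labels_by_cohort[[scheme$train_cohort_id]])
  X <- train$values[, names(train_labels), drop = FALSE]
  diff <- rowMeans(X[, train_labels, drop = FALSE]) -
    rowMeans(X[, !train_labels, drop = FALSE])
  tests <- lapply(scheme$test_cohort_ids, function(id) {
    lab <- assert_labels(labels_by_cohort[[id]])
    sub <- expression_cohort(cohorts[[id]]$values[, names(lab), drop = FALSE],
                             cohorts[[id]]$cohort_id, cohorts[[id]]$platform_id)
    list(cohort = sub, labels = lab, ranks = sample_ranks(sub))
  })
  names(tests) <- scheme$test_cohort_ids
  list(train = train, train_diff = diff, tests = tests)
}

eval_sets_cross <- function(ctx, sets) {
  lapply(sets, function(genes) {
    tryCatch({
      fit_genes <- intersect(genes, names(ctx$train_diff))
      if (!length(fit_genes)) stopf("gene set shares no genes with the training platform")
      dirs <- ifelse(ctx$train_diff[fit_genes] >= 0, 1L, -1L)
      lapply(ctx$tests, function(ts) {
        present <- fit_genes %in% ts$cohort$gene_ids
        if (!any(present)) stopf("gene set shares no genes with test platform '%s'",
                                 ts$cohort$platform_id)
        g <- fit_genes[present]
        d <- dirs[present]
        scores <- score_from_ranks(ts$ranks, g[d == 1L], g[d == -1L], nrow(ts$ranks))
        auc(scores, ts$labels)
      })
    }, error = function(e) e)
  })
}

as_gene_ids <- function(gene_set) {
  if (inherits(gene_set, "DirectionalSignature")) gene_set$gene_ids else as.character(gene_set)
}

set_label <- function(gene_set) {
  if (inherits(gene_set, "DirectionalSignature")) gene_set$name else "gene_set"
}

#' Flatten a validation result to a data frame
#' @param result a `ValidationResult`.
#' @return data.frame with unit_id, auc, n_cases, n_controls.
#' @export
validation_result_table <- function(result) {
  units <- result$per_unit_auc
  ids <- names(units)
  if (is.null(ids)) ids <- paste0("repeat_", seq_along(units))
  data.frame(unit_id = ids,
             auc = vapply(units, function(a) a$auc, 0),
             n_cases = vapply(units, function(a) a$n_cases, 0L),
             n_controls = vapply(units, function(a) a$n_controls, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
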