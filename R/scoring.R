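# Per-sample directional rank scoring and ROC AUC.

#' Within-sample rank matrix
#'
#' Ranks genes ascending by expression within each sample (column), ties given
#' average rank. Because ranking is per-sample, scores built on these ranks
#' are invariant to any monotone per-sample transform of the raw intensities —
#' which is what makes them portable across platforms and cohorts without
#' cross-cohort normalisation.
#'
#' @param cohort an [expression_cohort()] with at least 2 genes.
#' @return numeric matrix of ranks, same dimnames as the cohort values; each
#'   column sums to G(G+1)/2.
#' @export
sample_ranks <- function(cohort) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  if (length(cohort$gene_ids) < 2L) stopf("need at least 2 genes to rank")
  apply(cohort$values, 2L, rank)
}

#' Per-sample directional signature score
#'
#' For each sample, the score is the mean within-sample rank of the
#' signature's up-genes minus the mean rank of its down-genes, divided by the
#' number of ranked genes G:
#' \deqn{score_s = (\bar{r}_{up,s} - \bar{r}_{down,s}) / G}
#' A one-sided signature (no down-genes, or none present on the platform) is
#' centred instead: `mean(up ranks)/G - 0.5` (and symmetrically
#' `0.5 - mean(down ranks)/G`). Signature genes absent from the platform are
#' dropped with a warning when more than `min_overlap` of the signature is
#' missing — the two cohorts of a cross-platform benchmark rarely share full
#' gene content, so intersect-and-warn, not fail.
#'
#' @param cohort an [expression_cohort()].
#' @param signature a [directional_signature()].
#' @param ranks optional precomputed [sample_ranks()] matrix (full universe).
#' @param rank_within_signature rank only the signature's own genes instead of
#'   the whole platform. Non-default; the default full-array ranking means the
#'   rest of the transcriptome serves as the reference distribution.
#' @param min_overlap warn when the fraction of signature genes present on the
#'   platform falls below this threshold (default 0.5).
#' @return an object of class `ScoreVector`: `sample_ids`, `scores`,
#'   `signature_name`, `n_genes_used`, `n_genes_missing`.
#' @export
directional_score <- function(cohort, signature, ranks = NULL,
                              rank_within_signature = FALSE, min_overlap = 0.5) {
  stopifnot(inherits(cohort, "ExpressionCohort"), inherits(signature, "DirectionalSignature"))
  present <- signature$gene_ids %in% cohort$gene_ids
  if (!any(present)) {
    stopf("signature '%s' shares no genes with platform '%s'",
          signature$name, cohort$platform_id)
  }
  if (mean(present) < min_overlap) {
    warnf("signature '%s': only %d/%d genes present on platform '%s'",
          signature$name, sum(present), length(present), cohort$platform_id)
  }
  genes <- signature$gene_ids[present]
  dirs <- signature$directions[present]
  if (rank_within_signature) {
    sub <- expression_cohort(cohort$values[genes, , drop = FALSE],
                             cohort$cohort_id, cohort$platform_id)
    R <- sample_ranks(sub)
  } else {
    R <- if (is.null(ranks)) sample_ranks(cohort) else ranks
  }
  G <- nrow(R)
  up <- genes[dirs == 1L]
  down <- genes[dirs == -1L]
  scores <- score_from_ranks(R, up, down, G)
  structure(
    list(sample_ids = colnames(R), scores = scores, signature_name = signature$name,
         n_genes_used = length(genes), n_genes_missing = sum(!present)),
    class = "ScoreVector"
  )
}

# Core score arithmetic shared by directional_score and the vectorised
# null-evaluation path. `up`/`down` index rows of the rank matrix R.
score_from_ranks <- function(R, up, down, G = nrow(R)) {
  mean_rank <- function(g) {
    if (length(g) == 1L) R[g, ] else colMeans(R[g, , drop = FALSE])
  }
  if (length(up) && length(down)) {
    (mean_rank(up) - mean_rank(down)) / G
  } else if (length(up)) {
    mean_rank(up) / G - 0.5
  } else {
    0.5 - mean_rank(down) / G
  }
}

#' Fit gene directions from labelled expression data
#'
#' Data-driven direction assignment for a plain gene set: each gene's
#' direction is the sign of its mean log2 intensity in cases minus controls.
#' An exact zero difference gets direction +1 (deterministic tie-break,
#' reported via a message).
#'
#' @param cohort an [expression_cohort()].
#' @param labels named logical vector (TRUE = case) over a subset of the
#'   cohort's samples; both classes must be non-empty.
#' @param gene_set character vector of gene ids, a subset of the platform
#'   universe.
#' @param name name for the fitted signature.
#' @return a [directional_signature()].
#' @export
fit_directions <- function(cohort, labels, gene_set, name = "fitted") {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  assert_labels(labels)
  if (!all(names(labels) %in% cohort$sample_ids)) {
    stopf("labels reference samples absent from cohort '%s'", cohort$cohort_id)
  }
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, cohort$gene_ids)
  if (length(missing) == length(gene_set)) {
    stopf("gene_set shares no genes with platform '%s'", cohort$platform_id)
  }
  genes <- intersect(gene_set, cohort$gene_ids)
  X <- cohort$values[genes, names(labels), drop = FALSE]
  diff <- rowMeans(X[, labels, drop = FALSE]) - rowMeans(X[, !labels, drop = FALSE])
  n_tied <- sum(diff == 0)
  if (n_tied) message(sprintf("fit_directions: %d gene(s) with exactly zero difference assigned +1", n_tied))
  directional_signature(name, genes, ifelse(diff >= 0, 1L, -1L))
}

#' ROC AUC of a score against binary labels (Mann-Whitney form)
#'
#' AUC is the probability that a randomly chosen case scores above a randomly
#' chosen control, with ties credited 0.5:
#' \deqn{AUC = [\#(case > control) + 0.5\,\#(case = control)] / (n_1 n_0)}
#' computed via midranks. Cases are the positive class and are expected to
#' score higher.
#'
#' @param scores numeric score vector, or a `ScoreVector`.
#' @param labels logical vector aligned with scores (TRUE = case), or named
#'   and matched against a `ScoreVector`'s sample ids.
#' @return an object of class `AucResult`: `auc`, `n_cases`, `n_controls`,
#'   `n_tied_pairs`.
#' @export
auc <- function(scores, labels) {
  if (inherits(scores, "ScoreVector")) {
    if (!is.null(names(labels))) {
      if (!all(names(labels) %in% scores$sample_ids)) {
        stopf("labels reference samples absent from the score vector")
      }
      scores <- scores$scores[match(names(labels), scores$sample_ids)]
    } else {
      scores <- scores$scores
    }
  }
  if (!is.logical(labels)) stopf("labels must be logical (TRUE = case)")
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels contain NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L) stopf("no case samples")
  if (n0 == 0L) stopf("no control samples")
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  tied <- 0
  for (v in unique(scores[duplicated(scores)])) {
    tied <- tied + sum(labels & scores == v) * sum(!labels & scores == v)
  }
  structure(list(auc = u / (n1 * n0), n_cases = n1, n_controls = n0,
                 n_tied_pairs = as.integer(tied)),
            class = "AucResult")
}

#' @export
print.AucResult <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d cases vs %d controls, %d tied pairs)\n",
              x$auc, x$n_cases, x$n_controls, x$n_tied_pairs))
  invisible(x)
}

#' Write a score vector as TSV
#' @param score_vector a `ScoreVector`.
#' @param path output path.
#' @export
write_scores <- function(score_vector, path) {
  utils::write.table(
    data.frame(sample_id = score_vector$sample_ids, score = score_vector$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
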