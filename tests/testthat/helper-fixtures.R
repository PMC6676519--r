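# Fixture builders shared across test files. Everything is generated in code;
# no fixtures live on disk.

# A tiny cohort from an explicit matrix (genes x samples).
tiny_cohort <- function(values, cohort_id = "c1", platform_id = "p1",
                        gene_ids = sprintf("G%d", seq_len(nrow(values))),
                        sample_ids = sprintf("S%d", seq_len(ncol(values)))) {
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  expression_cohort(values, cohort_id, platform_id)
}

# Random cohort with iid noise, for property tests.
noise_cohort <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  tiny_cohort(matrix(rnorm(n_genes * n_samples, 8, sd), n_genes, n_samples))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force all-pairs AUC oracle (independent of the implementation).
brute_auc <- function(scores, labels) {
  cases <- scores[labels]
  controls <- scores[!labels]
  total <- 0
  for (x in cases) for (y in controls) {
    total <- total + (x > y) + 0.5 * (x == y)
  }
  total / (length(cases) * length(controls))
}

# Labels helper: named logical vector over a cohort's samples.
make_labels <- function(cohort, is_case) {
  stats::setNames(as.logical(is_case), cohort$sample_ids)
}
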