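# Expression cohorts, sample metadata, signatures, gene-set collections,
# exclusion lists, and sampling-pool construction.

#' Construct an expression cohort
#'
#' A cohort is one platform's genes x samples matrix of log2 intensities plus
#' identifying labels. Gene and sample identifiers are opaque strings; the
#' platform's gene universe is exactly the cohort's gene ids.
#'
#' @param values numeric matrix (genes in rows, samples in columns) with
#'   unique rownames (gene ids) and colnames (sample ids); no missing values.
#' @param cohort_id,platform_id text labels.
#' @return an object of class `ExpressionCohort` with fields `cohort_id`,
#'   `platform_id`, `values`, `gene_ids`, `sample_ids`.
#' @export
expression_cohort <- function(values, cohort_id, platform_id = cohort_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0L) stopf("no genes: expression matrix has zero rows")
  if (ncol(values) == 0L) stopf("no samples: expression matrix has zero columns")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("expression matrix must carry gene ids as rownames and sample ids as colnames")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stopf("missing expression value at gene '%s', sample '%s' (missing values are not imputed)",
          gene_ids[idx[1L]], sample_ids[idx[2L]])
  }
  structure(
    list(cohort_id = cohort_id, platform_id = platform_id, values = values,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "ExpressionCohort"
  )
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  cat(sprintf("ExpressionCohort '%s' (platform '%s'): %d genes x %d samples\n",
              x$cohort_id, x$platform_id, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Read an expression cohort from a tab-delimited file
#'
#' Expected layout: header row of sample ids, first column `gene_id`, numeric
#' log2-intensity body. Duplicated gene ids, non-numeric cells and missing
#' values are hard errors — rank scoring is undefined on missing data, so
#' nothing is imputed.
#'
#' @inheritParams expression_cohort
#' @param path file path.
#' @return an [expression_cohort()].
#' @export
read_expression_cohort <- function(path, cohort_id, platform_id = cohort_id) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stopf("'%s': expected gene_id column plus at least one sample", path)
  if (nrow(raw) == 0L) stopf("'%s': no genes (header only)", path)
  gene_ids <- raw[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("'%s': duplicate gene id(s): %s", path, paste(unique(dup), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  missing <- body == "" | toupper(body) == "NA"
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)[1L, ]
    stopf("'%s': missing value at row %d (gene '%s'), column '%s'",
          path, idx[1L], gene_ids[idx[1L]], colnames(body)[idx[2L]])
  }
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body), dimnames = dimnames(body)))
  bad <- is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("'%s': non-numeric value '%s' at row %d (gene '%s'), column '%s'",
          path, body[idx[1L], idx[2L]], idx[1L], gene_ids[idx[1L]], colnames(body)[idx[2L]])
  }
  rownames(num) <- gene_ids
  expression_cohort(num, cohort_id = cohort_id, platform_id = platform_id)
}

#' Write an expression cohort as tab-delimited text
#'
#' Values are serialised with 17 significant digits so a write/read round-trip
#' reproduces the matrix bit-exactly, in the same row and column order.
#'
#' @param cohort an [expression_cohort()].
#' @param path output path.
#' @export
write_expression_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  body <- apply(cohort$values, 2L, function(col) sprintf("%.17g", col))
  df <- data.frame(gene_id = cohort$gene_ids, body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", cohort$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited table with required columns `sample_id`, `cohort_id`, `age`,
#' `sex`, `diagnosis`, `batch`. Labels outside the declared universes are
#' rejected so that clinical-group selection never silently mislabels.
#'
#' @param path file path.
#' @param diagnosis_levels allowed diagnosis labels (default `CTL`, `MCI`, `AD`;
#'   pass e.g. `c("young", "old")` for age-classification cohorts).
#' @param sex_levels allowed sex labels.
#' @return a `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path, diagnosis_levels = c("CTL", "MCI", "AD"),
                                 sex_levels = c("F", "M")) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  required <- c("sample_id", "cohort_id", "age", "sex", "diagnosis", "batch")
  miss <- setdiff(required, colnames(md))
  if (length(miss)) stopf("'%s': missing required column(s): %s", path, paste(miss, collapse = ", "))
  validate_sample_metadata(md, diagnosis_levels, sex_levels)
}

validate_sample_metadata <- function(md, diagnosis_levels = c("CTL", "MCI", "AD"),
                                     sex_levels = c("F", "M")) {
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup)) stopf("duplicate sample_id(s): %s", paste(unique(dup), collapse = ", "))
  md$age <- as.numeric(md$age)
  if (anyNA(md$age) || any(md$age < 0)) stopf("age must be nonnegative and numeric for every sample")
  bad <- setdiff(unique(md$sex), sex_levels)
  if (length(bad)) stopf("unknown sex label(s): %s (allowed: %s)",
                         paste(bad, collapse = ", "), paste(sex_levels, collapse = ", "))
  bad <- setdiff(unique(md$diagnosis), diagnosis_levels)
  if (length(bad)) stopf("unknown diagnosis label(s): %s (allowed: %s)",
                         paste(bad, collapse = ", "), paste(diagnosis_levels, collapse = ", "))
  md$batch <- as.character(md$batch)
  md
}

#' Write sample metadata as tab-delimited text
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a directional signature
#'
#' A directional signature is a gene list in which every gene carries an
#' expected direction of change (+1 up, -1 down) in the condition of interest.
#'
#' @param name signature name.
#' @param gene_ids unique gene identifiers.
#' @param directions integer vector of +1/-1, one per gene.
#' @return an object of class `DirectionalSignature`.
#' @export
directional_signature <- function(name, gene_ids, directions) {
  if (length(gene_ids) < 1L) stopf("signature '%s' must contain at least one gene", name)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("signature '%s': duplicated gene id(s): %s",
                         name, paste(unique(dup), collapse = ", "))
  if (length(directions) != length(gene_ids)) stopf("one direction per gene required")
  directions <- as.integer(directions)
  if (!all(directions %in% c(-1L, 1L))) stopf("directions must be +1 or -1")
  structure(list(name = name, gene_ids = as.character(gene_ids), directions = directions),
            class = "DirectionalSignature")
}

#' @export
print.DirectionalSignature <- function(x, ...) {
  cat(sprintf("DirectionalSignature '%s': %d genes (%d up, %d down)\n",
              x$name, length(x$gene_ids), sum(x$directions == 1L), sum(x$directions == -1L)))
  invisible(x)
}

#' Read a directional signature from a two-column file
#'
#' Tab-delimited `gene_id<TAB>direction`, direction one of `+1`, `1`, `-1`,
#' `up`, `down`. A header line is detected and skipped.
#'
#' @param path file path.
#' @param name signature name; defaults to the file name without extension.
#' @return a [directional_signature()].
#' @export
read_signature <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stopf("signature file '%s' does not exist", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("'%s': empty signature file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stopf("'%s': line %d has fewer than 2 tab-separated fields", path, bad[1L])
  genes <- vapply(fields, `[[`, "", 1L)
  dirs <- tolower(trimws(vapply(fields, `[[`, "", 2L)))
  if (genes[1L] == "gene_id") { # header
    genes <- genes[-1L]; dirs <- dirs[-1L]
  }
  map <- c("+1" = 1L, "1" = 1L, "-1" = -1L, "up" = 1L, "down" = -1L)
  if (!all(dirs %in% names(map))) {
    stopf("'%s': unknown direction '%s' (allowed: +1, 1, -1, up, down)",
          path, dirs[!dirs %in% names(map)][1L])
  }
  directional_signature(name, genes, unname(map[dirs]))
}

#' Write a directional signature as a two-column file
#' @param signature a [directional_signature()].
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(
    data.frame(gene_id = signature$gene_ids, direction = signature$directions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One gene set per line: `name<TAB>description<TAB>gene<TAB>gene...`.
#' Duplicate genes within a line are deduplicated with a warning; duplicate
#' set names across lines are an error.
#'
#' @param path file path.
#' @return a named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stopf("'%s': empty GMT file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("'%s': line %d has fewer than 3 tab-separated fields", path, bad[1L])
  nm <- vapply(fields, `[[`, "", 1L)
  dup <- nm[duplicated(nm)]
  if (length(dup)) stopf("'%s': duplicated gene-set name(s): %s", path, paste(unique(dup), collapse = ", "))
  sets <- lapply(seq_along(fields), function(i) {
    genes <- fields[[i]][-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT set '%s': %d duplicate gene id(s) removed", nm[i], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = rep("na", length(sets))) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an exclusion gene list
#'
#' Plain text, one gene id per line; `#` starts a comment.
#'
#' @param path file path.
#' @return character vector of unique gene ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Construct a gene sampling pool
#'
#' A pool names the genes eligible for random gene-set sampling on one
#' platform. Provenance records how the pool was built: the whole array
#' (`all`), below-detection probes (`background`), detected probes
#' (`expressed`), or an exclusion-filtered universe (`filtered`).
#'
#' @param name pool name.
#' @param platform_id platform label.
#' @param gene_ids genes in the pool.
#' @param provenance one of `all`, `background`, `expressed`, `filtered`.
#' @param excluded genes removed from the pool (for `filtered` provenance).
#' @return an object of class `GenePool`.
#' @export
gene_pool <- function(name, platform_id, gene_ids,
                      provenance = c("all", "background", "expressed", "filtered"),
                      excluded = character()) {
  provenance <- match.arg(provenance)
  gene_ids <- unique(as.character(gene_ids))
  excluded <- unique(as.character(excluded))
  if (length(intersect(gene_ids, excluded))) {
    stopf("pool '%s': gene_ids and excluded sets overlap", name)
  }
  structure(list(name = name, platform_id = platform_id, gene_ids = gene_ids,
                 provenance = provenance, excluded = excluded),
            class = "GenePool")
}

#' @export
print.GenePool <- function(x, ...) {
  cat(sprintf("GenePool '%s' (%s, platform '%s'): %d genes, %d excluded\n",
              x$name, x$provenance, x$platform_id, length(x$gene_ids), length(x$excluded)))
  invisible(x)
}

#' Pool of all genes on a cohort's platform
#' @param cohort an [expression_cohort()].
#' @return a [gene_pool()] with provenance `all`.
#' @export
all_genes_pool <- function(cohort) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  gene_pool(paste0(cohort$platform_id, "_all"), cohort$platform_id,
            cohort$gene_ids, provenance = "all")
}

#' Background (below-detection) gene pool
#'
#' Microarray probes expressed below the detection floor carry no biology;
#' any class signal they show reflects technical (batch) variation. The pool
#' is defined as genes whose intensity falls below the `floor_quantile`
#' quantile of the cohort's pooled intensity distribution in at least
#' `sample_fraction` of samples. The quantile/fraction parameterisation is
#' this package's operationalisation of "non-expressed"; both knobs are
#' exposed because detection floors differ between platforms.
#'
#' @param cohort an [expression_cohort()].
#' @param floor_quantile q in (0,1): pooled-intensity quantile taken as the
#'   detection floor. Default 0.25.
#' @param sample_fraction f in (0,1]: minimum fraction of samples in which a
#'   gene must sit below the floor. Default 0.8.
#' @return a [gene_pool()] with provenance `background`.
#' @export
background_pool <- function(cohort, floor_quantile = 0.25, sample_fraction = 0.8) {
  stopifnot(inherits(cohort, "ExpressionCohort"))
  assert_scalar_number(floor_quantile, "floor_quantile", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(sample_fraction, "sample_fraction", 0, 1, strict_lower = TRUE)
  floor_val <- stats::quantile(cohort$values, probs = floor_quantile, names = FALSE)
  below <- rowMeans(cohort$values < floor_val)
  genes <- cohort$gene_ids[below >= sample_fraction]
  if (!length(genes)) {
    stopf("background pool is empty at floor_quantile=%g, sample_fraction=%g; raise the quantile or lower the fraction",
          floor_quantile, sample_fraction)
  }
  gene_pool(paste0(cohort$platform_id, "_background"), cohort$platform_id,
            genes, provenance = "background")
}

#' Exclusion-filtered gene pool
#'
#' Removes a stated list of genes (e.g. previously published age- and
#' disease-associated genes) from a sampling universe, so that "random"
#' gene-sets are random with respect to known biology.
#'
#' @param universe a [gene_pool()] or character vector of gene ids.
#' @param exclusion_list character vector of gene ids to remove.
#' @param platform_id required when `universe` is a character vector.
#' @param name pool name.
#' @return a [gene_pool()] with provenance `filtered` and the exclusions recorded.
#' @export
filtered_pool <- function(universe, exclusion_list, platform_id = NULL, name = NULL) {
  if (inherits(universe, "GenePool")) {
    genes <- universe$gene_ids
    platform_id <- universe$platform_id
    if (is.null(name)) name <- paste0(universe$name, "_filtered")
  } else {
    genes <- as.character(universe)
    if (is.null(platform_id)) stopf("platform_id required when universe is a plain gene vector")
    if (is.null(name)) name <- paste0(platform_id, "_filtered")
  }
  exclusion_list <- unique(as.character(exclusion_list))
  hit <- intersect(genes, exclusion_list)
  if (length(exclusion_list) && !length(hit)) {
    message(sprintf("filtered_pool '%s': exclusion list does not intersect the universe", name))
  }
  kept <- setdiff(genes, exclusion_list)
  if (!length(kept)) warnf("filtered_pool '%s' is empty: exclusion list covers the whole universe", name)
  gene_pool(name, platform_id, kept, provenance = "filtered", excluded = hit)
}

#' Intersect two gene pools across platforms
#'
#' Two arrays rarely share identical gene content, so a gene-set drawn from one
#' platform may be partly absent from the other. For paired evaluation (the
#' same random set scored on both cohorts) sampling is done from the
#' intersection of the two platform pools.
#'
#' @param a,b [gene_pool()] objects.
#' @param name name of the intersection pool.
#' @return a [gene_pool()] on the pseudo-platform `"<a>+<b>"`.
#' @export
intersect_pools <- function(a, b, name = paste0(a$name, "_x_", b$name)) {
  stopifnot(inherits(a, "GenePool"), inherits(b, "GenePool"))
  gene_pool(name, paste0(a$platform_id, "+", b$platform_id),
            intersect(a$gene_ids, b$gene_ids), provenance = a$provenance,
            excluded = union(a$excluded, b$excluded))
}
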