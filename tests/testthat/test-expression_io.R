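# Reading/writing expression matrices, metadata, signatures, gene sets,
# exclusion lists; background and filtered sampling pools.

expr_file <- function(header, rows) {
  write_lines_tmp(c(paste(header, collapse = "\t"),
                    vapply(rows, paste, "", collapse = "\t")), ext = ".tsv")
}

test_that("expression cohorts parse, validate and round-trip bit-exactly", {
  path <- expr_file(c("gene_id", "S1", "S2"),
                    list(c("G1", "1.5", "2.5"), c("G2", "0.25", "-1"), c("G3", "3", "4")))
  co <- read_expression_cohort(path, "c1", "p1")
  expect_equal(co$gene_ids, c("G1", "G2", "G3"))
  expect_equal(co$sample_ids, c("S1", "S2"))
  expect_equal(co$values["G2", "S2"], -1)

  # duplicate gene id names the offender
  dup <- expr_file(c("gene_id", "S1"), list(c("G1", "1"), c("G1", "2")))
  expect_error(read_expression_cohort(dup, "c"), "G1")
  # header-only file
  empty <- expr_file(c("gene_id", "S1"), list())
  expect_error(read_expression_cohort(empty, "c"), "no genes")
  # non-numeric cell located by gene and sample
  bad <- expr_file(c("gene_id", "S1", "S2"), list(c("G1", "1", "x")))
  expect_error(read_expression_cohort(bad, "c"), "G1.*S2")
  # missing values are never imputed
  na <- expr_file(c("gene_id", "S1", "S2"), list(c("G1", "1", "NA")))
  expect_error(read_expression_cohort(na, "c"), "missing")

  # round trip: awkward doubles survive exactly, order preserved
  set.seed(42)
  vals <- matrix(rnorm(60) * 10^sample(-3:3, 60, TRUE), 12, 5)
  co2 <- tiny_cohort(vals)
  out <- tempfile(fileext = ".tsv")
  write_expression_cohort(co2, out)
  back <- read_expression_cohort(out, "c1", "p1")
  expect_identical(back$values, co2$values)
  expect_identical(back$gene_ids, co2$gene_ids)
})

test_that("sample metadata enforces columns and label universes", {
  md_file <- function(rows) {
    write_lines_tmp(c("sample_id\tcohort_id\tage\tsex\tdiagnosis\tbatch", rows))
  }
  ok <- md_file(c("s1\tc1\t70\tF\tCTL\tb1", "s2\tc1\t71\tM\tAD\tb1",
                  "s3\tc1\t65\tF\tAD\tb2", "s4\tc1\t80\tM\tCTL\tb2"))
  md <- read_sample_metadata(ok)
  expect_equal(nrow(md), 4L)
  expect_type(md$age, "double")

  expect_error(read_sample_metadata(md_file("s1\tc1\t70\tX\tCTL\tb1")), "sex")
  expect_error(read_sample_metadata(md_file(c("s1\tc1\t70\tF\tCTL\tb1",
                                              "s1\tc1\t70\tF\tAD\tb1"))), "duplicate")
  expect_error(read_sample_metadata(md_file("s1\tc1\t70\tF\tweird\tb1")), "diagnosis")
  # alternative declared label universe is accepted
  md2 <- read_sample_metadata(md_file(c("s1\tc1\t20\tF\tyoung\tb1",
                                        "s2\tc1\t70\tM\told\tb1")),
                              diagnosis_levels = c("young", "old"))
  expect_equal(md2$diagnosis, c("young", "old"))
  # missing required column is named
  nc <- write_lines_tmp(c("sample_id\tcohort_id\tage\tsex\tdiagnosis",
                          "s1\tc1\t70\tF\tCTL"))
  expect_error(read_sample_metadata(nc), "batch")
})

test_that("GMT parsing handles dedup, malformed lines and name clashes", {
  p <- write_lines_tmp(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tB\tD"))
  sets <- read_gmt(p)
  expect_equal(sets, list(S1 = c("A", "B", "C"), S2 = c("B", "D")))

  expect_warning(dups <- read_gmt(write_lines_tmp("S1\tdesc\tA\tA\tB")), "duplicate")
  expect_equal(dups$S1, c("A", "B"))
  expect_error(read_gmt(write_lines_tmp(c("S1\tdesc\tA", "S2\tonlydesc"))), "line 2")
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S1\td\tB"))), "S1")

  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)
})

test_that("signatures parse directions and reject duplicates", {
  p <- write_lines_tmp(c("gene_id\tdirection", "A\tup", "B\tdown", "C\t+1", "D\t-1"))
  sig <- read_signature(p, "s")
  expect_equal(sig$directions, c(1L, -1L, 1L, -1L))
  expect_error(directional_signature("x", c("A", "A"), c(1, -1)), "duplicated")
  expect_error(directional_signature("x", character(), integer()), "at least one")
  expect_error(directional_signature("x", "A", 2), "\\+1 or -1")
  out <- tempfile()
  write_signature(sig, out)
  expect_equal(read_signature(out, "s"), sig)
})

test_that("exclusion lists strip comments and blanks", {
  p <- write_lines_tmp(c("# known age genes", "G1", "", "G2  ", "G1", "G3 # inline"))
  expect_equal(read_exclusion_list(p), c("G1", "G2", "G3"))
})

test_that("background pool matches a direct threshold-count oracle", {
  # 100 genes pinned at the detection floor, 300 clearly expressed
  set.seed(7)
  vals <- rbind(matrix(rnorm(100 * 30, 4, 0.2), 100, 30),
                matrix(rnorm(300 * 30, 9, 1.0), 300, 30))
  co <- tiny_cohort(vals)
  pool <- background_pool(co, floor_quantile = 0.3, sample_fraction = 0.9)
  # oracle: recount below-threshold fractions directly
  thr <- quantile(vals, 0.3, names = FALSE)
  oracle <- rownames(co$values)[rowMeans(co$values < thr) >= 0.9]
  expect_setequal(pool$gene_ids, oracle)
  expect_true(all(sprintf("G%d", 1:100) %in% pool$gene_ids))
  expect_equal(pool$provenance, "background")

  # each gene high in at least one sample + f = 1 leaves nothing
  v2 <- matrix(4, 10, 10) + diag(10) * 100
  expect_error(background_pool(tiny_cohort(v2), 0.5, 1.0), "empty")
  # q near 1 approaches the whole universe
  pool_all <- background_pool(co, 0.999, 0.5)
  expect_gt(length(pool_all$gene_ids), 390)
})

test_that("background pool is monotone in its two knobs", {
  co <- noise_cohort(200, 25, seed = 3)
  qs <- c(0.1, 0.25, 0.5, 0.8)
  sizes_q <- vapply(qs, function(q) {
    length(tryCatch(background_pool(co, q, 0.4)$gene_ids, error = function(e) character()))
  }, 0L)
  expect_true(all(diff(sizes_q) >= 0))
  fs <- c(0.2, 0.4, 0.6, 0.9)
  sizes_f <- vapply(fs, function(f) {
    length(tryCatch(background_pool(co, 0.5, f)$gene_ids, error = function(e) character()))
  }, 0L)
  expect_true(all(diff(sizes_f) <= 0))
})

test_that("filtered pools are exact set differences with recorded exclusions", {
  uni <- gene_pool("u", "p1", c("A", "B", "C", "D", "E"), "all")
  fp <- filtered_pool(uni, c("B", "D"))
  expect_setequal(fp$gene_ids, c("A", "C", "E"))
  expect_equal(fp$provenance, "filtered")
  expect_setequal(fp$excluded, c("B", "D"))
  # invariants: pool union exclusions covers the universe; disjoint
  expect_true(all(uni$gene_ids %in% union(fp$gene_ids, fp$excluded)))
  expect_length(intersect(fp$gene_ids, fp$excluded), 0)

  # empty exclusion list keeps everything, provenance still filtered
  expect_message(fp0 <- filtered_pool(uni, character()), NA)
  expect_setequal(fp0$gene_ids, uni$gene_ids)
  expect_equal(fp0$provenance, "filtered")
  # exclusion covering the universe empties the pool with a warning
  expect_warning(fpx <- filtered_pool(uni, LETTERS[1:5]), "empty")
  expect_length(fpx$gene_ids, 0)
})

test_that("pool intersection restricts to shared gene content", {
  a <- gene_pool("a", "p1", c("A", "B", "C"), "all")
  b <- gene_pool("b", "p2", c("B", "C", "D"), "all")
  ab <- intersect_pools(a, b)
  expect_setequal(ab$gene_ids, c("B", "C"))
  expect_equal(ab$platform_id, "p1+p2")
})
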