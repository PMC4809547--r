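test_that("BED6 and narrowPeak sites parse with BED coordinate conventions", {
  p <- write_tmp(c("chr1\t100\t119\tsiteA\t900\t+",
                   "chr2\t500\t520\tsiteB\t10\t?"), ".bed")
  s <- read_sites(p, "bed6")
  expect_equal(s$chrom, c("chr1", "chr2"))
  expect_equal(s$start, c(100L, 500L))
  expect_equal(s$end, c(119L, 520L))
  expect_equal(s$strand, c("+", "."))   # unknown strand stored as "."
  expect_true(all(is.na(s$summit_offset)))

  np <- write_tmp(c("chr1\t100\t119\tpk1\t900\t.\t5.5\t3.2\t2.1\t9",
                    "chr1\t300\t350\tpk2\t800\t.\t5.5\t3.2\t2.1\t-1"), ".narrowPeak")
  s2 <- read_sites(np, "narrowPeak")
  expect_equal(s2$summit_offset, c(9L, NA_integer_))
})

test_that("malformed or invalid site lines fail with the offending line number", {
  p <- write_tmp(c("chr1\t100\t119\ta\t0\t+", "chr1\t50\t50\tb\t0\t+"), ".bed")
  expect_error(read_sites(p, "bed6"), "line 2.*\\[50, 50\\)")
  p2 <- write_tmp(c("chr1\t100\t119\ta\t0\t+", "chr1\t100"), ".bed")
  expect_error(read_sites(p2, "bed6"), "line 2")
  p3 <- write_tmp("chr1\t-5\t10\ta\t0\t+", ".bed")
  expect_error(read_sites(p3, "bed6"), "line 1")
  p4 <- write_tmp("chr1\tabc\t10\ta\t0\t+", ".bed")
  expect_error(read_sites(p4, "bed6"), "non-integer")
})

test_that("BEDPE mates merge to the outer span; over-length and cross-chromosome pairs are dropped and counted", {
  p <- write_tmp(c(
    "chr2\t100\t150\tchr2\t230\t280\tf1\t0\t+\t-",   # span 180, kept
    "chr2\t100\t150\tchr2\t650\t700\tf2\t0\t+\t-",   # span 600 > 500, dropped
    "chr2\t100\t150\tchr3\t230\t280\tf3\t0\t+\t-"),  # cross-chromosome, dropped
    ".bedpe")
  r <- read_fragments(p, "bedpe", max_length = 500L)
  expect_equal(nrow(r$fragments), 1L)
  expect_equal(r$fragments$start, 100L)
  expect_equal(r$fragments$end, 280L)
  expect_equal(r$n_dropped, 2L)

  empty <- write_tmp(character(0), ".bedpe")
  r0 <- read_fragments(empty, "bedpe", max_length = 500L)
  expect_equal(nrow(r0$fragments), 0L)
  expect_equal(r0$n_dropped, 0L)
})

test_that("kept fragments always satisfy 1 <= length <= max_length", {
  set.seed(5)
  start <- sample.int(10000, 200)
  mate2 <- start + sample.int(700, 200)
  lines <- sprintf("chr1\t%d\t%d\tchr1\t%d\t%d\tf\t0\t+\t-",
                   start, start + 50, mate2, mate2 + 50)
  r <- read_fragments(write_tmp(lines, ".bedpe"), "bedpe", max_length = 300L)
  len <- r$fragments$end - r$fragments$start
  expect_true(all(len >= 1 & len <= 300))
  expect_equal(nrow(r$fragments) + r$n_dropped, 200L)  # kept + dropped partition the input
})

test_that("site and fragment writers round-trip through their readers", {
  sites <- toy_sites(c(1000, 3000, 5000))
  p <- withr::local_tempfile(fileext = ".bed")
  write_sites(sites, p)
  back <- read_sites(p, "bed6")
  expect_equal(back[, c("chrom", "start", "end", "name", "strand")],
               sites[, c("chrom", "start", "end", "name", "strand")])

  frags <- toy_fragments(c(100, 250, 400), c(247, 420, 549))
  pf <- withr::local_tempfile(fileext = ".bedpe")
  write_fragments(frags, pf)
  rf <- read_fragments(pf, "bedpe", max_length = 500L)
  expect_equal(rf$fragments, frags)
  expect_equal(rf$n_dropped, 0L)
})

test_that("DE tables parse, deduplicate with a warning, and reject bad numbers", {
  p <- write_tmp(c("gene_id\tfold_change\tp_value\tq_value",
                   "GENE1\t2.0\t0.001\t0.01",
                   "GENE2\t0.5\t0.2\t0.5"), ".tsv")
  t1 <- read_de_table(p)
  expect_equal(t1$gene_id, c("GENE1", "GENE2"))
  expect_equal(t1$fold_change, c(2.0, 0.5))

  pdup <- write_tmp(c("gene_id\tfold_change\tp_value\tq_value",
                      "GENE1\t2.0\t0.001\t0.01",
                      "GENE1\t3.0\t0.002\t0.02"), ".tsv")
  expect_warning(td <- read_de_table(pdup), "duplicate")
  expect_equal(nrow(td), 1L)
  expect_equal(td$fold_change, 2.0)   # first occurrence kept

  pbad <- write_tmp(c("gene_id\tfold_change\tp_value\tq_value",
                      "GENE1\tNA\t0.001\t0.01"), ".tsv")
  expect_error(read_de_table(pbad), "non-numeric fold_change")
})

test_that("profile files round-trip to 1e-9 and reject non-contiguous positions", {
  prof <- toy_profile(abs(sin(1:2001)) + 0.1, rescaled_mean = 1,
                      n_sites = 12L, total_fragments = 3456L,
                      smoothing_bp = 51L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, p)
  expect_equal(length(readLines(p)), 2002L)   # header + one row per base
  back <- read_profile(p)
  expect_equal(back$values, prof$values, tolerance = 1e-9)
  expect_equal(back$n_sites, prof$n_sites)
  expect_equal(back$total_fragments, prof$total_fragments)
  expect_equal(back$smoothing_bp, prof$smoothing_bp)

  lines <- readLines(p)
  writeLines(lines[-5], p)            # delete one base: gap in positions
  expect_error(read_profile(p), "not contiguous")
})
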