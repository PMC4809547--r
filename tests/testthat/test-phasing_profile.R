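# brute-force oracle: double loop over (dyad, anchor) pairs
oracle_aggregate <- function(dyads, anchors, half_window) {
  counts <- integer(2L * half_window + 1L)
  for (i in seq_len(nrow(dyads))) {
    for (j in seq_len(nrow(anchors))) {
      if (dyads$chrom[i] != anchors$chrom[j]) next
      o <- (dyads$pos[i] - anchors$anchor[j]) * anchors$sign[j]
      if (abs(o) <= half_window) counts[o + half_window + 1L] <-
          counts[o + half_window + 1L] + 1L
    }
  }
  counts
}

mk_anchors <- function(pos, chrom = "chr1", sign = 1L) {
  data.frame(chrom = chrom, anchor = as.integer(pos), sign = sign,
             stringsAsFactors = FALSE)
}

test_that("aggregation counts dyad-anchor offsets, sharing dyads between overlapping windows", {
  dy <- data.frame(chrom = "chr1", pos = c(4900L, 5000L, 5100L))
  raw <- aggregate_dyads(dy, mk_anchors(5000), 1000)
  off <- profile_offsets(raw)
  expect_equal(off[raw$counts > 0], c(-100L, 0L, 100L))
  expect_true(all(raw$counts[raw$counts > 0] == 1L))

  # one dyad inside two overlapping windows is counted once per window
  dy2 <- data.frame(chrom = "chr1", pos = 1500L)
  raw2 <- aggregate_dyads(dy2, mk_anchors(c(1000, 2000)), 1000)
  expect_equal(sum(raw2$counts), 2L)

  dy3 <- data.frame(chrom = "chr1", pos = c(900L, 1000L, 1900L, 2100L, 3500L))
  raw3 <- aggregate_dyads(dy3, mk_anchors(c(1000, 2000)), 200)
  expect_equal(sum(raw3$counts), 4L)
  off3 <- profile_offsets(raw3)
  expect_equal(raw3$counts[match(c(-100L, 0L, 100L), off3)], c(2L, 1L, 1L))
})

test_that("aggregation equals the brute-force double loop on random instances", {
  set.seed(23)
  for (rep in 1:4) {
    dy <- data.frame(chrom = sample(c("chr1", "chr2"), 400, replace = TRUE),
                     pos = sample.int(20000, 400, replace = TRUE),
                     stringsAsFactors = FALSE)
    an <- mk_anchors(sample.int(20000, 8),
                     chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                     sign = sample(c(-1L, 1L), 8, replace = TRUE))
    hw <- sample(c(150L, 500L), 1)
    expect_identical(aggregate_dyads(dy, an, hw)$counts,
                     oracle_aggregate(dy, an, hw))
  }
})

test_that("normalization divides by depth and site count, then forces the window mean", {
  raw <- nucphasing:::new_raw_profile(c(1L, 2L, 3L, 2L, 1L), 2L, 3L, 100L)
  p <- normalize_profile(raw, 1)
  expect_equal(p$values, c(5, 10, 15, 10, 5) / 9)
  expect_equal(mean(p$values), 1, tolerance = 1e-12)

  flat <- normalize_profile(nucphasing:::new_raw_profile(rep(7L, 5), 2L, 2L, 10L), 1)
  expect_equal(flat$values, rep(1, 5))

  doubled <- nucphasing:::new_raw_profile(2L * raw$counts, 2L, 3L, 100L)
  expect_equal(normalize_profile(doubled, 1)$values, p$values)   # scale invariance

  expect_equal(normalize_profile(p, 1)$values, p$values)         # idempotent
  expect_error(normalize_profile(
    nucphasing:::new_raw_profile(rep(0L, 5), 2L, 1L, 1L)), "no signal")
})

test_that("smoothing is a mean-preserving centered box filter with shrinking edges", {
  const <- toy_profile(rep(2, 101), rescaled_mean = 2)
  expect_equal(smooth_profile(const, 50)$values, rep(2, 101))

  tiny <- toy_profile(c(0, 0, 5, 0, 0), rescaled_mean = 1)
  sm <- smooth_profile(tiny, 3)
  expect_equal(sm$values, c(0, 5 / 3, 5 / 3, 5 / 3, 0))
  expect_equal(sm$smoothing_bp, 3L)

  imp <- toy_profile(c(rep(0, 100), 1, rep(0, 100)), rescaled_mean = 1 / 201)
  smi <- smooth_profile(imp, 50)                  # even window promoted to 51
  expect_equal(smi$smoothing_bp, 51L)
  off <- profile_offsets(smi)
  inside <- abs(off) <= 25
  expect_equal(length(unique(round(smi$values[inside], 12))), 1L)  # plateau
  expect_true(all(smi$values[!inside] == 0))

  set.seed(41)
  p <- toy_profile(runif(2001), rescaled_mean = 1.7)
  p <- normalize_profile(p, 1.7)
  expect_equal(mean(smooth_profile(p, 50)$values), 1.7, tolerance = 1e-9)

  expect_error(smooth_profile(tiny, 9), "exceeds")
})

test_that("central occupancy averages the central band and tracks site-centered nucleosomes", {
  flat <- toy_profile(rep(1, 2001), rescaled_mean = 1)
  expect_equal(occupancy_in_center(flat), 1.0)

  off <- -1000:1000
  bump <- toy_profile(1 + 2 * exp(-off^2 / (2 * 50^2)))
  expect_gt(occupancy_in_center(bump), mean(bump$values))

  # CTCF-depleted cohorts leave sites vacant, gaining central occupancy
  run_center <- function(name) {
    r <- run_scenario_cohort(scenario_presets(seed = 19)[[name]], n_sites = 400)
    occupancy_in_center(r$profile)
  }
  expect_gt(run_center("ctcf_depleted"), run_center("control"))
})

test_that("the noiseless pipeline puts profile maxima exactly on the generator lattice", {
  res <- run_scenario_cohort(noiseless_spec(seed = 10), n_sites = 200)
  expect_equal(res$peaks$peak_offsets, lattice_offsets(280, 176, 10, 1000))
})
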