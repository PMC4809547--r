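test_that("peak detection recovers cosine extrema and applies the separation tie rule", {
  off <- -1000:1000
  cosine <- toy_profile(2 + cos(2 * pi * off / 250))
  pk <- detect_peaks(cosine, min_separation = 120)
  expect_equal(pk$peak_offsets, c(-750, -500, -250, 0, 250, 500, 750))

  # two equal maxima 60 bp apart: one kept, smaller |offset| wins
  v <- rep(0, 201); v[101 + 30] <- 5; v[101 + 90] <- 5
  tie <- detect_peaks(toy_profile(v), min_separation = 120)
  expect_equal(tie$peak_offsets, 30)

  flat <- toy_profile(rep(1, 201))
  expect_length(detect_peaks(flat)$peak_offsets, 0L)
})

test_that("prominence threshold suppresses ripple relative to profile s.d.", {
  off <- -1000:1000
  v <- 2 + cos(2 * pi * off / 250) + 0.05 * cos(2 * pi * off / 40)
  pk <- detect_peaks(toy_profile(v), prominence_frac = 0.25,
                     min_separation = 120)
  expect_equal(pk$peak_offsets, c(-750, -500, -250, 0, 250, 500, 750),
               tolerance = 0.05)
})

test_that("phasing summary computes +1/-1 distance and per-flank regression NRL", {
  mk_peaks <- function(offs) structure(
    list(peak_offsets = offs, prominences = rep(1, length(offs)),
         prominence_threshold = 0), class = "peak_set")
  prof <- toy_profile(rep(1, 2001))

  s <- summarize_phasing(prof, mk_peaks(c(-303, -127, 127, 303, 479)))
  expect_equal(s$plus_one, 127)
  expect_equal(s$minus_one, -127)
  expect_equal(s$p1m1_distance, 254)
  expect_equal(s$nrl_right, 176)             # slope through 127, 303, 479
  expect_equal(s$nrl_left, 176)

  r <- summarize_phasing(prof, mk_peaks(c(150, 330)))
  expect_equal(r$nrl_right, 180)
  expect_equal(r$nrl, 180)
  expect_true(is.na(r$p1m1_distance))

  # translation of one flank leaves the slope unchanged
  base <- summarize_phasing(prof, mk_peaks(c(140, 316, 492)))
  shif <- summarize_phasing(prof, mk_peaks(c(140, 316, 492) + 37))
  expect_equal(base$nrl_right, shif$nrl_right)

  expect_error(summarize_phasing(prof, mk_peaks(numeric(0))), "no peaks")
})

test_that("NRL regression equals the generator lattice exactly in the noiseless limit", {
  for (nrl in c(160, 176, 198)) {
    res <- run_scenario_cohort(noiseless_spec(seed = 2, nrl = nrl),
                               n_sites = 150)
    expect_equal(res$summary$nrl, nrl)
    expect_equal(res$summary$p1m1_distance, 280)
  }
})

test_that("cohort NRL and preset differences are recovered within 2 bp", {
  est <- function(name, seeds) {
    sapply(seeds, function(s) {
      r <- run_scenario_cohort(scenario_presets(seed = s)[[name]], n_sites = 1000)
      c(r$summary$nrl, r$summary$p1m1_distance)
    })
  }
  ctrl <- est("control", 1:3)
  snf2h <- est("snf2h_depleted", 1:3)
  expect_lt(abs(mean(ctrl[1, ]) - 176), 2)
  expect_lt(abs(mean(snf2h[1, ]) - 183), 2)
  expect_lt(abs(mean(snf2h[1, ] - ctrl[1, ]) - 7), 2)
  expect_lt(abs(mean(snf2h[2, ] - ctrl[2, ]) - 25), 3)
})

test_that("condition comparison is antisymmetric and reports the spacing deltas", {
  flat <- toy_profile(rep(1, 2001))
  mk <- function(p1m1, nrl, prof = flat) list(
    summary = list(p1m1_distance = p1m1, nrl = nrl), profile = prof)

  same <- compare_conditions(mk(280, 176), mk(280, 176))
  expect_equal(same$delta_p1m1, 0)
  expect_equal(same$delta_nrl, 0)
  expect_equal(same$delta_center_occupancy, 0)

  up <- compare_conditions(mk(280, 176), mk(305, 183))
  expect_equal(up$delta_nrl, 7)            # 176 -> 183 under SNF2H depletion
  expect_equal(up$delta_p1m1, 25)
  down <- compare_conditions(mk(280, 176), mk(270, 173))
  expect_equal(down$delta_nrl, -3)         # 176 -> 173 under SNF2L depletion

  rev <- compare_conditions(mk(305, 183), mk(280, 176))
  expect_equal(rev$delta_p1m1, -up$delta_p1m1)
  expect_equal(rev$delta_nrl, -up$delta_nrl)

  expect_error(compare_conditions(mk(NA, 176), mk(280, 176)),
               "missing p1m1")
  expect_warning(
    compare_conditions(mk(280, 176), mk(280, 176),
                       digestion = list(matched = FALSE, delta_mean = 22,
                                        tolerance = 5)),
    "not comparable")
})

test_that("occupancy change reports percent reduction of background-subtracted enrichment", {
  off <- -1000:1000
  band <- as.numeric(abs(off) <= 73)
  ctrl <- toy_profile(1 + 2 * band)
  expect_equal(occupancy_change(ctrl, ctrl), 0)
  halfp <- toy_profile(1 + 1 * band)
  expect_equal(occupancy_change(ctrl, halfp), 50)
  expect_error(occupancy_change(toy_profile(rep(1, 2001)), ctrl),
               "zero control")
})

test_that("simulated ChIP depletion cohorts show the closed-form enrichment loss", {
  sites <- simulate_sites(100, 1.2e6, 5000, seed = 21)
  anchors <- site_anchors(sites)
  prof <- function(enr, seed) {
    fr <- simulate_chip_fragments(sites, enrichment = enr, peak_sd = 100,
                                  n_fragments = 3e5, seed = seed)
    normalize_profile(aggregate_dyads(fragment_midpoints(fr), anchors, 1000))
  }
  # enrichment above background scales with (E - 1): (9 - 3.6) / 9 = 60%
  chg <- occupancy_change(prof(10, 31), prof(4.6, 32))
  expect_lt(abs(chg - 60), 5)
})
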