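# Builders for small in-code fixtures shared across test files.

toy_profile <- function(values, rescaled_mean = mean(values),
                        n_sites = 1L, total_fragments = 1L,
                        smoothing_bp = 0L) {
  stopifnot(length(values) %% 2L == 1L)
  nucphasing:::new_dyad_profile(values, (length(values) - 1L) %/% 2L,
                                n_sites, total_fragments, smoothing_bp,
                                rescaled_mean)
}

toy_sites <- function(centers, chrom = "chr1", width = 19L) {
  start <- as.integer(centers - width %/% 2L)
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("s%d", seq_along(centers)), score = 0,
             strand = ".", summit_offset = NA_integer_,
             stringsAsFactors = FALSE)
}

toy_fragments <- function(start, end, chrom = "chr1") {
  data.frame(chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# scenario with every noise source off: fragments fall exactly on the
# generator's dyad lattice
noiseless_spec <- function(seed = 1L, nrl = 176, plus_one_distance = 280,
                           n_per_side = 10L, dyads_per_site = 30) {
  scenario_spec("control",
                array_model(nrl = nrl, plus_one_distance = plus_one_distance,
                            n_per_side = n_per_side, jitter_sd0 = 0,
                            jitter_growth = 0, background_rate = 0,
                            bound_fraction = 1),
                digestion_model(core_bp = 147L, overhang_mean = 0,
                                dyads_per_site = dyads_per_site),
                seed = seed)
}

# deterministic offsets of the dyad lattice visible inside a window
lattice_offsets <- function(plus_one_distance = 280, nrl = 176,
                            n_per_side = 10L, half_window = 1000L) {
  d <- plus_one_distance / 2 + (seq_len(n_per_side) - 1L) * nrl
  d <- d[d <= half_window]
  sort(c(-d, d))
}

write_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
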