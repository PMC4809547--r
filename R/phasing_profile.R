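# Per-base normalized, smoothed dyad metaprofiles around aligned site
# anchors: the computation behind every nucleosome/ChIP density plot.

new_raw_profile <- function(counts, half_window, n_sites, total_fragments) {
  structure(list(counts = as.integer(counts),
                 half_window = as.integer(half_window),
                 n_sites = as.integer(n_sites),
                 total_fragments = as.integer(total_fragments)),
            class = "raw_profile")
}

new_dyad_profile <- function(values, half_window, n_sites, total_fragments,
                             smoothing_bp, rescaled_mean) {
  structure(list(values = as.numeric(values),
                 half_window = as.integer(half_window),
                 n_sites = as.integer(n_sites),
                 total_fragments = as.integer(total_fragments),
                 smoothing_bp = as.integer(smoothing_bp),
                 rescaled_mean = as.numeric(rescaled_mean)),
            class = "dyad_profile")
}

#' Profile offsets
#'
#' @param profile A `raw_profile` or `dyad_profile`.
#' @return Integer offsets `-half_window .. +half_window`.
#' @export
profile_offsets <- function(profile) {
  seq.int(-profile$half_window, profile$half_window)
}

#' @export
print.dyad_profile <- function(x, ...) {
  cat(sprintf(
    "Dyad profile: window +/-%d bp (%d bases), %d sites, %d fragments, smoothing %d bp, mean %.3g\n",
    x$half_window, 2L * x$half_window + 1L, x$n_sites, x$total_fragments,
    x$smoothing_bp, x$rescaled_mean))
  invisible(x)
}

#' Aggregate dyad counts around site anchors
#'
#' Counts, for every offset `o` in `-half_window .. +half_window`, the
#' (dyad, anchor) pairs on the same chromosome with
#' `(dyad - anchor) * sign = o`. A dyad falling inside two overlapping site
#' windows contributes to both.
#'
#' @param dyads Dyad table (`chrom`, `pos`) from [fragment_midpoints()].
#' @param anchors Anchor table from [site_anchors()].
#' @param half_window Window half-width (bp); the window spans
#'   `2 * half_window + 1` bases including both endpoints.
#' @return A `raw_profile`; `total_fragments` is the total dyad count of the
#'   experiment (in or out of windows).
#' @export
aggregate_dyads <- function(dyads, anchors, half_window = 1000L) {
  stopifnot(nrow(anchors) >= 1)
  half_window <- as.integer(half_window)
  nbin <- 2L * half_window + 1L
  counts <- integer(nbin)
  for (ch in unique(anchors$chrom)) {
    pos <- sort(dyads$pos[dyads$chrom == ch])
    if (!length(pos)) next
    ai <- which(anchors$chrom == ch)
    for (i in ai) {
      a <- anchors$anchor[i]
      lo <- findInterval(a - half_window - 1L, pos) + 1L
      hi <- findInterval(a + half_window, pos)
      if (hi < lo) next
      off <- (pos[lo:hi] - a) * anchors$sign[i]
      counts <- counts + tabulate(off + half_window + 1L, nbins = nbin)
    }
  }
  new_raw_profile(counts, half_window, nrow(anchors), nrow(dyads))
}

#' Normalize a profile to library depth, site count, and a common mean
#'
#' Two steps: (1) divide each per-base count by `n_sites * total_fragments`,
#' making conditions with different sequencing depths and site counts
#' comparable; (2) scale by a single constant so the window mean equals
#' `rescaled_mean`, so plotted conditions share the same mean level. Applied
#' to an already-normalized profile it only redoes step 2 (idempotent for
#' the same `rescaled_mean`).
#'
#' @param raw A `raw_profile` (or a `dyad_profile` to re-rescale).
#' @param rescaled_mean Target window mean.
#' @return A `dyad_profile`.
#' @export
normalize_profile <- function(raw, rescaled_mean = 1.0) {
  if (inherits(raw, "dyad_profile")) {
    v <- raw$values
    smoothing <- raw$smoothing_bp
  } else if (inherits(raw, "raw_profile")) {
    v <- raw$counts / (raw$n_sites * as.numeric(raw$total_fragments))
    smoothing <- 0L
  } else {
    stop("normalize_profile expects a raw_profile or dyad_profile", call. = FALSE)
  }
  m <- mean(v)
  if (m <= 0) stop("no signal in window: cannot rescale an all-zero profile", call. = FALSE)
  new_dyad_profile(v * (rescaled_mean / m), raw$half_window, raw$n_sites,
                   raw$total_fragments, smoothing, rescaled_mean)
}

#' Smooth a profile with a centered sliding window
#'
#' Centered moving average for graphical and peak-detection use. An even
#' `window_bp` is incremented to the next odd value so the filter is
#' symmetric (50 -> 51). At the window edges the averaging window shrinks
#' symmetrically to fit; a final rescale restores the profile's
#' `rescaled_mean` exactly.
#'
#' @param profile A `dyad_profile`.
#' @param window_bp Smoothing window (bp).
#' @return A smoothed `dyad_profile` with `smoothing_bp` recorded.
#' @export
smooth_profile <- function(profile, window_bp = 50L) {
  stopifnot(inherits(profile, "dyad_profile"), window_bp >= 1)
  window_bp <- as.integer(window_bp)
  if (window_bp %% 2L == 0L) window_bp <- window_bp + 1L
  n <- length(profile$values)
  if (window_bp > n) {
    stop(sprintf("smoothing window (%d) exceeds the profile length (%d)",
                 window_bp, n), call. = FALSE)
  }
  half <- (window_bp - 1L) %/% 2L
  idx <- seq_len(n)
  k <- pmin(half, idx - 1L, n - idx)          # symmetric shrink at edges
  cs <- cumsum(c(0, profile$values))
  sm <- (cs[idx + k + 1L] - cs[idx - k]) / (2 * k + 1)
  out <- new_dyad_profile(sm, profile$half_window, profile$n_sites,
                          profile$total_fragments, window_bp,
                          profile$rescaled_mean)
  normalize_profile(out, profile$rescaled_mean)
}

#' Mean occupancy in the central band
#'
#' Average normalized density over `|offset| <= center_halfwidth`, the band
#' covering a site-centered nucleosome (73 bp = half a 147 bp core by
#' default). Rises when vacant sites gain a nucleosome.
#'
#' @param profile A `dyad_profile`.
#' @param center_halfwidth Half-width of the central band (bp).
#' @return Mean value over the band.
#' @export
occupancy_in_center <- function(profile, center_halfwidth = 73L) {
  stopifnot(center_halfwidth <= profile$half_window)
  off <- profile_offsets(profile)
  mean(profile$values[abs(off) <= center_halfwidth])
}
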