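# Phasing quantification: peak calling on metaprofiles, +1/-1 distance,
# nucleosome repeat length by per-flank regression, and condition deltas.

#' Detect phased nucleosome peaks in a metaprofile
#'
#' Finds local maxima (plateaus collapse to their central base, ties toward
#' the smaller offset), computes each candidate's topographic prominence and
#' discards candidates below `prominence_frac` times the profile s.d. (a
#' threshold invariant to the mean-rescaling choice). Each surviving
#' candidate's position is then refined to the baseline-subtracted centroid
#' of the profile in a symmetric window of half-width
#' `floor(min_separation / 2)` — a box-smoothed narrow peak has a nearly
#' flat top whose raw argmax wanders with noise, while the centroid locates
#' the underlying dyad position to the base pair. Refined candidates are
#' kept greedily in decreasing prominence order subject to a pairwise
#' separation of at least `min_separation` bp; prominence ties break toward
#' the smaller absolute offset. Maxima at the window edges are not reported.
#'
#' @param profile A `dyad_profile`, normally smoothed first.
#' @param prominence_frac Prominence threshold as a fraction of the profile
#'   s.d.
#' @param min_separation Minimum distance between reported peaks (bp);
#'   default 120, below the smallest plausible repeat but above smoothing
#'   ripple spacing.
#' @return A `peak_set` list: `peak_offsets` (increasing bp offsets, refined
#'   so possibly non-integer), `prominences` (matching order) and
#'   `prominence_threshold`.
#' @export
detect_peaks <- function(profile, prominence_frac = 0.25,
                         min_separation = 120L) {
  stopifnot(inherits(profile, "dyad_profile"), prominence_frac >= 0)
  v <- profile$values
  off <- profile_offsets(profile)
  n <- length(v)
  empty <- structure(list(peak_offsets = numeric(0), prominences = numeric(0),
                          prominence_threshold = prominence_frac * stats::sd(v)),
                     class = "peak_set")
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3L) return(empty)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  is_max <- c(FALSE, r$values[2:(nr - 1)] > r$values[1:(nr - 2)] &
                r$values[2:(nr - 1)] > r$values[3:nr], FALSE)
  if (!any(is_max)) return(empty)
  peak_idx <- vapply(which(is_max), function(j) {
    run_start[j] + (r$lengths[j] - 1L) %/% 2L
  }, integer(1))
  prom <- vapply(peak_idx, function(i) peak_prominence(v, i), numeric(1))
  thr <- prominence_frac * stats::sd(v)
  keep <- prom >= thr
  peak_idx <- peak_idx[keep]
  prom <- prom[keep]
  if (!length(peak_idx)) return(empty)
  half <- as.integer(min_separation) %/% 2L
  # pre-merge: a noisy plateau top yields several near-coincident candidates;
  # keep only the most prominent within half the separation radius
  ord <- order(-prom, abs(off[peak_idx]), off[peak_idx])
  surv <- integer(0)
  for (i in ord) {
    if (all(abs(off[peak_idx[i]] - off[peak_idx[surv]]) >= half)) {
      surv <- c(surv, i)
    }
  }
  peak_idx <- peak_idx[sort(surv)]
  prom <- prom[sort(surv)]
  pos <- vapply(seq_along(peak_idx), function(j) {
    i <- peak_idx[j]
    gap <- abs(off[peak_idx[-j]] - off[i])
    k <- min(half, i - 1L, n - i,          # symmetric so the centroid is unbiased
             if (length(gap)) min(gap) %/% 2L else half)
    w <- v[(i - k):(i + k)] - min(v[(i - k):(i + k)])
    if (sum(w) == 0) return(as.numeric(off[i]))
    sum(off[(i - k):(i + k)] * w) / sum(w)
  }, numeric(1))
  # greedy selection on refined positions: decreasing prominence,
  # ties -> smaller |offset|
  ord <- order(-prom, abs(pos), pos)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(pos[i] - pos[sel]) >= min_separation)) sel <- c(sel, i)
  }
  o <- order(pos[sel])
  structure(list(peak_offsets = pos[sel][o],
                 prominences = prom[sel][o],
                 prominence_threshold = thr),
            class = "peak_set")
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles toward the nearest higher ground (or edge)
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]
  j <- i
  while (j > 1L && v[j - 1L] <= v[i]) {
    j <- j - 1L
    if (v[j] < left_min) left_min <- v[j]
  }
  right_min <- v[i]
  j <- i
  while (j < n && v[j + 1L] <= v[i]) {
    j <- j + 1L
    if (v[j] < right_min) right_min <- v[j]
  }
  v[i] - max(left_min, right_min)
}

#' Summarize phasing from detected peaks
#'
#' Per flank, the nucleosome repeat length (NRL) is the least-squares slope
#' of peak distance from the anchor regressed on peak index (1, 2, ...
#' counting outward, up to `max_peaks_per_side` peaks) — using every peak
#' makes the estimate robust to a single missed peak, unlike adjacent
#' differences. `adjacent_diff_nrl` is reported alongside as a cross-check.
#'
#' @param profile The `dyad_profile` the peaks came from.
#' @param peaks A `peak_set` from [detect_peaks()].
#' @param max_peaks_per_side Maximum peaks used per flank.
#' @param center_exclude Peaks with `|offset| <= center_exclude` are treated
#'   as the site-centered nucleosome (occupancy of a vacant site), not as
#'   flanking array peaks; 73 bp = half a nucleosome core, safely below any
#'   +1/-1 half-distance.
#' @return A `phasing_summary` list: `plus_one`, `minus_one`,
#'   `p1m1_distance`, `nrl_left`, `nrl_right`, `nrl`,
#'   `n_peaks_used_per_side`, `adjacent_diff_nrl`, `amplitude`.
#' @export
summarize_phasing <- function(profile, peaks, max_peaks_per_side = 10L,
                              center_exclude = 73) {
  stopifnot(inherits(peaks, "peak_set"))
  offs <- peaks$peak_offsets[abs(peaks$peak_offsets) > center_exclude]
  right <- offs[offs > 0]
  left <- sort(-offs[offs < 0])        # distances from anchor, outward order
  if (!length(right) && !length(left)) {
    stop("no peaks on either flank: phasing summary undefined", call. = FALSE)
  }
  flank_nrl <- function(dist) {
    k <- min(length(dist), max_peaks_per_side)
    if (k < 2L) return(NA_real_)
    x <- seq_len(k)
    y <- dist[x]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  nrl_right <- flank_nrl(right)
  nrl_left <- flank_nrl(left)
  nrl <- mean(c(nrl_left, nrl_right), na.rm = TRUE)
  adj <- c(diff(right[seq_len(min(length(right), max_peaks_per_side))]),
           diff(left[seq_len(min(length(left), max_peaks_per_side))]))
  structure(list(
    plus_one = if (length(right)) right[1] else NA_integer_,
    minus_one = if (length(left)) -left[1] else NA_integer_,
    p1m1_distance = if (length(right) && length(left)) right[1] + left[1] else NA_real_,
    nrl_left = nrl_left, nrl_right = nrl_right,
    nrl = if (is.nan(nrl)) NA_real_ else nrl,
    n_peaks_used_per_side = c(left = min(length(left), max_peaks_per_side),
                              right = min(length(right), max_peaks_per_side)),
    adjacent_diff_nrl = if (length(adj)) mean(adj) else NA_real_,
    amplitude = stats::sd(profile$values)),
    class = "phasing_summary")
}

#' @export
print.phasing_summary <- function(x, ...) {
  cat(sprintf("Phasing: +1 at %s, -1 at %s, +1/-1 distance %s bp, NRL %s bp (L %s / R %s)\n",
              fmt_bp(x$plus_one), fmt_bp(x$minus_one), fmt_bp(x$p1m1_distance),
              fmt_bp(x$nrl), fmt_bp(x$nrl_left), fmt_bp(x$nrl_right)))
  invisible(x)
}

fmt_bp <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", as.numeric(x))

#' Compare phasing between two conditions
#'
#' Elementwise differences (experimental minus control) of the +1/-1
#' distance, the repeat length, and the central occupancy statistic.
#' Digestion matching is the caller's responsibility upstream; pass
#' `digestion` (a [digestion_match()] result) to have a mismatch re-flagged
#' as a warning here.
#'
#' @param control,experimental Lists with elements `summary` (a
#'   `phasing_summary`) and `profile` (a `dyad_profile`).
#' @param center_halfwidth Central band half-width for the occupancy delta.
#' @param digestion Optional [digestion_match()] verdict for the two
#'   underlying samples.
#' @return A `condition_delta` list: `delta_p1m1`, `delta_nrl`,
#'   `delta_center_occupancy`.
#' @export
compare_conditions <- function(control, experimental, center_halfwidth = 73L,
                               digestion = NULL) {
  for (side in list(c("control", "p1m1_distance"), c("control", "nrl"),
                    c("experimental", "p1m1_distance"), c("experimental", "nrl"))) {
    val <- (if (side[1] == "control") control else experimental)$summary[[side[2]]]
    if (is.null(val) || is.na(val)) {
      stop(sprintf("%s summary is missing %s", side[1], side[2]), call. = FALSE)
    }
  }
  if (!is.null(digestion) && !digestion$matched) {
    warning(sprintf("digestion mismatch (delta mean %.1f bp > %.0f bp): conditions not comparable",
                    digestion$delta_mean, digestion$tolerance), call. = FALSE)
  }
  structure(list(
    delta_p1m1 = experimental$summary$p1m1_distance - control$summary$p1m1_distance,
    delta_nrl = experimental$summary$nrl - control$summary$nrl,
    delta_center_occupancy = occupancy_in_center(experimental$profile, center_halfwidth) -
      occupancy_in_center(control$profile, center_halfwidth)),
    class = "condition_delta")
}

#' Percent change in background-subtracted central occupancy
#'
#' Quantifies loss of ChIP enrichment: for each profile the background is
#' the mean over the outermost 10% of the window on each side, the occupancy
#' statistic is the central-band mean above background relative to that
#' background (a normalization-invariant fold enrichment), and the result is
#' `100 * (control - experimental) / control` — positive = reduction.
#'
#' @param control_profile,experimental_profile `dyad_profile`s sharing
#'   `half_window`.
#' @param center_halfwidth Central band half-width (bp).
#' @return Signed percent change.
#' @export
occupancy_change <- function(control_profile, experimental_profile,
                             center_halfwidth = 73L) {
  if (control_profile$half_window != experimental_profile$half_window) {
    stop("profiles must share half_window", call. = FALSE)
  }
  enrich <- function(p) {
    v <- p$values
    n <- length(v)
    k <- max(1L, as.integer(round(0.1 * n)))
    bg <- mean(c(v[seq_len(k)], v[seq.int(n - k + 1L, n)]))
    if (bg <= 0) stop("zero background: enrichment undefined", call. = FALSE)
    (occupancy_in_center(p, center_halfwidth) - bg) / bg
  }
  ec <- enrich(control_profile)
  if (ec <= 0) {
    stop("zero control central signal after background subtraction", call. = FALSE)
  }
  100 * (ec - enrich(experimental_profile)) / ec
}
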