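# Dyad extraction and digestion-extent quantification.

#' Fragment midpoints (dyad proxies)
#'
#' The midpoint of a nucleosomal paired-end fragment approximates the
#' nucleosome dyad. Midpoint = `start + floor((end - start) / 2)`; the floor
#' makes even-length fragments deterministic so profiles are reproducible to
#' the base pair.
#'
#' @param fragments Fragment table (`chrom`, `start`, `end`).
#' @return A `data.frame` with `chrom` and `pos`, one dyad per fragment,
#'   input order preserved.
#' @export
fragment_midpoints <- function(fragments) {
  data.frame(chrom = fragments$chrom,
             pos = interval_center(fragments$start, fragments$end),
             stringsAsFactors = FALSE)
}

#' Fragment length statistics
#'
#' Mean fragment length measures the extent of MNase digestion: complete
#' digestion trims fragments to the 147 bp nucleosome core, lighter digestion
#' leaves linker overhangs and longer means.
#'
#' @param fragments Fragment table with at least one row.
#' @return A `length_stats` list: `n`, `mean_length`, `mode_length`
#'   (smallest length among ties) and `histogram` (named integer vector,
#'   length -> count).
#' @export
length_stats <- function(fragments) {
  if (nrow(fragments) == 0L) stop("no fragments: length statistics undefined", call. = FALSE)
  len <- fragments$end - fragments$start
  tab <- table(len)
  counts <- as.integer(tab)
  lens <- as.integer(names(tab))
  structure(list(n = length(len),
                 mean_length = sum(as.numeric(lens) * counts) / length(len),
                 mode_length = lens[which.max(counts)],
                 histogram = stats::setNames(counts, lens)),
            class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("Fragment length stats: n=%d mean=%.2f bp mode=%d bp\n",
              x$n, x$mean_length, x$mode_length))
  invisible(x)
}

#' Digestion matching between two samples
#'
#' Two samples are comparable only when their mean fragment lengths differ by
#' at most `tolerance` (5 bp by default): differential digestion alone shifts
#' nucleosome profiles and would confound any between-condition comparison.
#' The boundary is inclusive.
#'
#' @param a,b `length_stats` objects.
#' @param tolerance Maximum allowed difference in mean length (bp).
#' @return A list: `matched` (logical), `delta_mean` (absolute difference,
#'   bp) and `tolerance`.
#' @export
digestion_match <- function(a, b, tolerance = 5) {
  stopifnot(inherits(a, "length_stats"), inherits(b, "length_stats"))
  delta <- abs(a$mean_length - b$mean_length)
  list(matched = delta <= tolerance, delta_mean = delta, tolerance = tolerance)
}
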