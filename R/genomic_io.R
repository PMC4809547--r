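# Readers/writers for the interval, fragment and table formats the pipeline
# touches. All genomic coordinates are 0-based half-open (BED convention).

#' Read transcription-factor binding sites from BED6 or narrowPeak
#'
#' Parses an interval file into a site table with strict validation. BED6
#' gives chrom/start/end/name/score/strand; ENCODE narrowPeak adds
#' signalValue/pValue/qValue and a summit offset in column 10 (-1 = absent).
#' Coordinates are kept 0-based half-open exactly as in the file.
#'
#' @param path Path to the file.
#' @param format One of `"bed6"` or `"narrowPeak"`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` and `summit_offset` (`NA` when absent), rows in file
#'   order.
#' @export
read_sites <- function(path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  ncol_req <- if (format == "bed6") 6L else 10L
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) return(empty_sites())
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_req)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected %d tab-separated columns, found %d",
                 lines$lineno[bad[1]], path, ncol_req, nf[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_req)))
  start <- parse_int_col(m[, 2], lines$lineno, path, "start")
  end <- parse_int_col(m[, 3], lines$lineno, path, "end")
  validate_intervals(start, end, lines$lineno, path)
  strand <- m[, 6]
  strand[!strand %in% c("+", "-")] <- "."
  summit <- rep(NA_integer_, length(start))
  if (format == "narrowPeak") {
    summit <- parse_int_col(m[, 10], lines$lineno, path, "summit offset")
    width <- end - start
    ok <- summit == -1L | (summit >= 0L & summit < width)
    if (any(!ok)) {
      i <- which(!ok)[1]
      stop(sprintf("validation error at line %d of %s: summit offset %d outside [0, %d)",
                   lines$lineno[i], path, summit[i], width[i]), call. = FALSE)
    }
    summit[summit == -1L] <- NA_integer_
  }
  data.frame(chrom = m[, 1], start = start, end = end,
             name = m[, 4], score = suppressWarnings(as.numeric(m[, 5])),
             strand = strand, summit_offset = summit,
             stringsAsFactors = FALSE)
}

#' Write sites as BED6
#'
#' @param sites Site table as returned by [read_sites()] or
#'   [simulate_sites()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  score <- sites$score
  score[is.na(score)] <- 0
  df <- data.frame(sites$chrom, sites$start, sites$end, sites$name,
                   score, sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired-end fragments from BEDPE or BED3
#'
#' BEDPE mates are merged to the outer span `[min(start1, start2),
#' max(end1, end2))` — the sequenced insert between the outermost mate ends.
#' Fragments longer than `max_length` and inter-chromosomal mate pairs are
#' dropped and counted, mirroring the aligner's maximum-fragment-length cap
#' (500 bp for nucleosomal, 1500 bp for ChIP libraries).
#'
#' @param path Path to the file.
#' @param format One of `"bedpe"` or `"bed3"`.
#' @param max_length Maximum fragment length kept (bp).
#' @return A list with `fragments` (data.frame `chrom`, `start`, `end` in
#'   file order) and `n_dropped` (over-length plus inter-chromosomal).
#' @export
read_fragments <- function(path, format = c("bedpe", "bed3"),
                           max_length = 500L) {
  format <- match.arg(format)
  stopifnot(max_length >= 1)
  ncol_req <- if (format == "bedpe") 6L else 3L
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(list(fragments = empty_fragments(), n_dropped = 0L))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_req)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected at least %d columns, found %d",
                 lines$lineno[bad[1]], path, ncol_req, nf[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_req)))
  if (format == "bed3") {
    start <- parse_int_col(m[, 2], lines$lineno, path, "start")
    end <- parse_int_col(m[, 3], lines$lineno, path, "end")
    validate_intervals(start, end, lines$lineno, path)
    chrom <- m[, 1]
    cross <- rep(FALSE, length(start))
  } else {
    s1 <- parse_int_col(m[, 2], lines$lineno, path, "start1")
    e1 <- parse_int_col(m[, 3], lines$lineno, path, "end1")
    s2 <- parse_int_col(m[, 5], lines$lineno, path, "start2")
    e2 <- parse_int_col(m[, 6], lines$lineno, path, "end2")
    validate_intervals(s1, e1, lines$lineno, path)
    validate_intervals(s2, e2, lines$lineno, path)
    chrom <- m[, 1]
    cross <- m[, 1] != m[, 4]
    start <- pmin(s1, s2)
    end <- pmax(e1, e2)
  }
  over <- (end - start) > max_length
  drop <- cross | over
  list(fragments = data.frame(chrom = chrom[!drop], start = start[!drop],
                              end = end[!drop], stringsAsFactors = FALSE),
       n_dropped = sum(drop))
}

#' Write fragments as 10-column BEDPE
#'
#' Each fragment is emitted as a synthetic mate pair covering its outermost
#' ends (50 bp reads, shortened for sub-100 bp fragments), so that
#' [read_fragments()] merging recovers the original interval exactly.
#'
#' @param fragments Fragment table (`chrom`, `start`, `end`).
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(is.data.frame(fragments))
  len <- fragments$end - fragments$start
  rlen <- pmin(50L, len)
  df <- data.frame(fragments$chrom, fragments$start, fragments$start + rlen,
                   fragments$chrom, fragments$end - rlen, fragments$end,
                   sprintf("frag_%d", seq_len(nrow(fragments))),
                   0L, "+", "-")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a tab-delimited file whose header names the columns `gene_id`,
#' `fold_change` (linear scale), `p_value` and `q_value`. Duplicate gene ids
#' keep the first occurrence with a warning.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the four columns, one row per gene.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character"))
  req <- c("gene_id", "fold_change", "p_value", "q_value")
  if (!all(req %in% names(df))) {
    stop(sprintf("DE table %s must have header columns: %s",
                 path, paste(req, collapse = ", ")), call. = FALSE)
  }
  df <- df[, req]
  for (col in req[-1]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error in %s: non-numeric %s at data row %d",
                   path, col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (any(df$fold_change <= 0)) stop("fold_change must be > 0", call. = FALSE)
  if (any(df$p_value < 0 | df$p_value > 1) || any(df$q_value < 0 | df$q_value > 1)) {
    stop("p_value and q_value must lie in [0, 1]", call. = FALSE)
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate gene_id rows in %s; keeping first occurrence",
                    sum(dup), path), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a differential-expression table
#'
#' @param table DE table with columns `gene_id`, `fold_change`, `p_value`,
#'   `q_value`.
#' @param path Output path.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(table[, c("gene_id", "fold_change", "p_value", "q_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dyad profile as two-column TSV
#'
#' Emits a comment header recording the normalization constants and per-base
#' rows `offset<TAB>value` over the full contiguous window, round-trippable
#' by [read_profile()].
#'
#' @param profile A `dyad_profile` (see [normalize_profile()]).
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dyad_profile"))
  h <- profile$half_window
  off <- seq.int(-h, h)
  if (length(profile$values) != length(off)) {
    stop("profile positions are not contiguous over the window", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# nsites=%d total_fragments=%d half_window=%d smoothing_bp=%d rescaled_mean=%.17g",
    profile$n_sites, profile$total_fragments, h, profile$smoothing_bp,
    profile$rescaled_mean), con)
  writeLines(sprintf("%d\t%.17g", off, profile$values), con)
  invisible(path)
}

#' Read a dyad profile written by [write_profile()]
#'
#' @param path Path to the profile TSV.
#' @return A `dyad_profile` object.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  if (is.na(hdr)) stop("profile file lacks its '# nsites=...' header", call. = FALSE)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eg+]+", hdr))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                          vapply(kv, `[`, "", 1))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  off <- as.integer(vapply(parts, `[`, "", 1))
  v <- as.numeric(vapply(parts, `[`, "", 2))
  h <- as.integer(vals[["half_window"]])
  if (!identical(off, seq.int(-h, h))) {
    stop("profile positions are not contiguous over the window", call. = FALSE)
  }
  new_dyad_profile(values = v, half_window = h,
                  n_sites = as.integer(vals[["nsites"]]),
                  total_fragments = as.integer(vals[["total_fragments"]]),
                  smoothing_bp = as.integer(vals[["smoothing_bp"]]),
                  rescaled_mean = vals[["rescaled_mean"]])
}

# -- internal parsing helpers -------------------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path)
  keep <- nzchar(raw) & !startsWith(raw, "#") &
    !startsWith(raw, "track") & !startsWith(raw, "browser")
  list(text = raw[keep], lineno = which(keep))
}

parse_int_col <- function(x, lineno, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: non-integer %s '%s'",
                 lineno[bad[1]], path, what, x[bad[1]]), call. = FALSE)
  }
  v
}

validate_intervals <- function(start, end, lineno, path) {
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    stop(sprintf("validation error at line %d of %s: invalid interval [%d, %d)",
                 lineno[bad[1]], path, start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             summit_offset = integer(), stringsAsFactors = FALSE)
}

empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}
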