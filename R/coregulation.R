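# Co-regulation analysis: DE-table filtering, gene-set overlap significance,
# and effect-size concordance between two depletions.

#' Select differentially regulated genes
#'
#' A gene is kept iff its fold change exceeds the threshold in either
#' direction (`fc > t` or `fc < 1/t`), its uncorrected p-value is below
#' `p_max` and its FDR-adjusted q-value is below `q_max`. All inequalities
#' are strict.
#'
#' @param table DE table ([read_de_table()] layout).
#' @param fc_threshold Linear fold-change threshold (> 1).
#' @param p_max,q_max Significance cutoffs.
#' @return Character vector of gene ids.
#' @export
filter_significant <- function(table, fc_threshold = 1.5, p_max = 0.05,
                               q_max = 0.05) {
  stopifnot(fc_threshold > 1)
  keep <- (table$fold_change > fc_threshold |
             table$fold_change < 1 / fc_threshold) &
    table$p_value < p_max & table$q_value < q_max
  table$gene_id[keep]
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of observing at least the realized intersection
#' when `n_a` and `n_b` genes are drawn without replacement from a common
#' universe — the over-representation test for co-regulated genes. The tail
#' is summed in log space, so p-values far below double underflow (the
#' co-regulation overlaps reach below 1e-50) are computed accurately.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector: genes measured in both experiments.
#' @return An `overlap_result` list: `n_universe`, `n_a`, `n_b`, `n_shared`,
#'   `hypergeom_p`, `log10_p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be contained in the universe", call. = FALSE)
  }
  n <- length(universe)
  na <- length(set_a)
  nb <- length(set_b)
  k <- length(intersect(set_a, set_b))
  lp <- hyper_upper_log(k, na, nb, n)
  structure(list(n_universe = n, n_a = na, n_b = nb, n_shared = k,
                 hypergeom_p = exp(lp), log10_p = lp / log(10)),
            class = "overlap_result")
}

# log P(X >= k), X ~ Hypergeometric(n, na, nb), by logsumexp over the tail
hyper_upper_log <- function(k, na, nb, n) {
  hi <- min(na, nb)
  if (k <= max(0L, na + nb - n)) return(0)        # certain event
  if (k > hi) return(-Inf)
  logs <- stats::dhyper(k:hi, na, n - na, nb, log = TRUE)
  m <- max(logs)
  min(0, m + log(sum(exp(logs - m))))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: %d shared of %d vs %d (universe %d), hypergeometric p = %.3g (log10 p = %.1f)\n",
              x$n_shared, x$n_a, x$n_b, x$n_universe, x$hypergeom_p, x$log10_p))
  invisible(x)
}

#' Concordance of fold changes over shared genes
#'
#' Spearman rank correlation of signed log2 fold changes across the shared
#' gene set, with average ranks for ties and a p-value from the large-sample
#' t approximation (two-sided).
#'
#' @param table_a,table_b DE tables.
#' @param shared Character vector of gene ids present in both tables.
#' @return List with `spearman_rho`, `spearman_p` and `n`.
#' @export
concordance <- function(table_a, table_b, shared) {
  shared <- unique(shared)
  if (length(shared) < 3L) {
    stop("need at least 3 shared genes for rank correlation", call. = FALSE)
  }
  la <- log2(table_a$fold_change[match(shared, table_a$gene_id)])
  lb <- log2(table_b$fold_change[match(shared, table_b$gene_id)])
  if (anyNA(la) || anyNA(lb)) {
    stop("some shared genes are missing from a table", call. = FALSE)
  }
  n <- length(shared)
  rho <- stats::cor(rank(la), rank(lb))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(spearman_rho = rho, spearman_p = p, n = n)
}

#' Full co-regulation analysis of two DE tables
#'
#' Universe = genes measured in both tables; significant sets by
#' [filter_significant()]; overlap by [overlap_test()]; concordance over the
#' shared significant genes when at least 3 exist.
#'
#' @param table_a,table_b DE tables.
#' @inheritParams filter_significant
#' @return An `overlap_result` with `spearman_rho` and `spearman_p` added
#'   (`NA` when fewer than 3 shared genes).
#' @export
coregulation_analysis <- function(table_a, table_b, fc_threshold = 1.5,
                                  p_max = 0.05, q_max = 0.05) {
  universe <- intersect(table_a$gene_id, table_b$gene_id)
  in_uni <- function(tab) tab[tab$gene_id %in% universe, , drop = FALSE]
  ta <- in_uni(table_a); tb <- in_uni(table_b)
  set_a <- filter_significant(ta, fc_threshold, p_max, q_max)
  set_b <- filter_significant(tb, fc_threshold, p_max, q_max)
  res <- overlap_test(set_a, set_b, universe)
  shared <- intersect(set_a, set_b)
  if (length(shared) >= 3L) {
    cc <- concordance(ta, tb, shared)
    res$spearman_rho <- cc$spearman_rho
    res$spearman_p <- cc$spearman_p
  } else {
    res$spearman_rho <- NA_real_
    res$spearman_p <- NA_real_
  }
  res
}
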