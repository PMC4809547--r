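# Synthetic phased-chromatin generator: barrier-model nucleosome arrays
# around bound factor sites, digestion-dependent fragment lengths, ChIP
# enrichment peaks, and paired differential-expression tables.

#' Nucleosome array model around a bound-factor barrier
#'
#' Parameters of the barrier model: a stably bound factor restricts
#' nucleosome positions, organising arrays outward on both flanks. Dyads sit
#' at `+/-(plus_one_distance/2 + k * nrl)` for array index `k = 0, 1, ...`,
#' with placement noise whose s.d. grows linearly with `k` — reproducing the
#' decay of phasing away from the barrier.
#'
#' @param nrl Nucleosome repeat length (bp), the center-to-center spacing
#'   within a flank.
#' @param plus_one_distance Center-to-center distance between the +1 and -1
#'   dyads across the site (bp); must be at least one nucleosome core.
#' @param n_per_side Nucleosomes per flank.
#' @param jitter_sd0 Placement s.d. of the +1/-1 dyads (bp).
#' @param jitter_growth Additional placement s.d. per array index (bp).
#' @param background_rate Background dyads per bp per site window.
#' @param bound_fraction Fraction of sites occupied by the factor.
#' @return An `array_model` list.
#' @export
array_model <- function(nrl = 176, plus_one_distance = 280, n_per_side = 10L,
                        jitter_sd0 = 2, jitter_growth = 1,
                        background_rate = 0.002, bound_fraction = 0.95) {
  stopifnot(nrl > 0, plus_one_distance >= 147, n_per_side >= 1,
            jitter_sd0 >= 0, jitter_growth >= 0, background_rate >= 0,
            bound_fraction >= 0, bound_fraction <= 1)
  structure(list(nrl = nrl, plus_one_distance = plus_one_distance,
                 n_per_side = as.integer(n_per_side),
                 jitter_sd0 = jitter_sd0, jitter_growth = jitter_growth,
                 background_rate = background_rate,
                 bound_fraction = bound_fraction),
            class = "array_model")
}

#' MNase digestion model
#'
#' The nucleosome core protects 147 bp; incomplete digestion leaves linker
#' overhangs on each side, modelled as independent geometric lengths so the
#' mean fragment length is `core_bp + 2 * overhang_mean` (147 bp at complete
#' digestion, 169 bp at `overhang_mean = 11`).
#'
#' @param core_bp Protected core length (bp).
#' @param overhang_mean Mean single-sided linker overhang (bp).
#' @param dyads_per_site Expected phased dyads sampled per bound site.
#' @return A `digestion_model` list.
#' @export
digestion_model <- function(core_bp = 147L, overhang_mean = 0,
                            dyads_per_site = 30) {
  stopifnot(core_bp >= 1, overhang_mean >= 0, dyads_per_site > 0)
  structure(list(core_bp = as.integer(core_bp), overhang_mean = overhang_mean,
                 dyads_per_site = dyads_per_site),
            class = "digestion_model")
}

#' Scenario specification
#'
#' Bundles an array model, a digestion model and a seed under one of the
#' four named study conditions.
#'
#' @param name One of `"control"`, `"snf2h_depleted"`, `"snf2l_depleted"`,
#'   `"ctcf_depleted"`.
#' @param array An [array_model()].
#' @param digestion A [digestion_model()].
#' @param seed Integer seed for all randomness of a simulation call.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, array = array_model(),
                          digestion = digestion_model(), seed = 1L) {
  name <- match.arg(name, c("control", "snf2h_depleted", "snf2l_depleted",
                            "ctcf_depleted"))
  stopifnot(inherits(array, "array_model"), inherits(digestion, "digestion_model"))
  structure(list(name = name, array = array, digestion = digestion,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Preset scenarios for the study conditions
#'
#' The four conditions share all parameters except those each depletion
#' perturbs:
#' * `control` — repeat length 176 bp (the CTCF-adjacent spacing).
#' * `snf2h_depleted` — repeat length 183 bp, +1/-1 distance widened by
#'   25 bp, and larger jitter growth (loss of phasing away from the site).
#' * `snf2l_depleted` — repeat length 173 bp, +1/-1 distance narrowed by
#'   10 bp.
#' * `ctcf_depleted` — barrier largely unoccupied (`bound_fraction` drops),
#'   so vacant sites gain a site-centered nucleosome.
#'
#' @param seed Seed stored in each preset (override per run as needed).
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  ctrl <- array_model(nrl = 176, plus_one_distance = 280)
  dig <- digestion_model()
  list(
    control = scenario_spec("control", ctrl, dig, seed),
    snf2h_depleted = scenario_spec(
      "snf2h_depleted",
      array_model(nrl = 183, plus_one_distance = ctrl$plus_one_distance + 25,
                  jitter_growth = 3),
      dig, seed),
    snf2l_depleted = scenario_spec(
      "snf2l_depleted",
      array_model(nrl = 173, plus_one_distance = ctrl$plus_one_distance - 10),
      dig, seed),
    ctcf_depleted = scenario_spec(
      "ctcf_depleted",
      array_model(nrl = 176, plus_one_distance = ctrl$plus_one_distance,
                  bound_fraction = 0.3),
      dig, seed)
  )
}

#' Simulate non-overlapping factor binding sites
#'
#' Places `n_sites` 19 bp sites uniformly on a single synthetic chromosome
#' with pairwise center distance at least `min_gap`.
#'
#' @param n_sites Number of sites.
#' @param chrom_length Chromosome length (bp).
#' @param min_gap Minimum center-to-center distance (bp).
#' @param seed Integer seed.
#' @param width Site width (bp).
#' @param chrom Chromosome name.
#' @return Site table in [read_sites()] layout.
#' @export
simulate_sites <- function(n_sites, chrom_length, min_gap = 5000L, seed = 1L,
                           width = 19L, chrom = "chrS") {
  n_sites <- as.integer(n_sites)
  span <- (n_sites - 1L) * min_gap + width + min_gap
  if (n_sites * min_gap >= chrom_length || span > chrom_length) {
    stop(sprintf("cannot pack %d sites with min_gap %d into %d bp",
                 n_sites, min_gap, chrom_length), call. = FALSE)
  }
  withr::with_seed(seed, {
    slack <- chrom_length - width - (n_sites - 1L) * min_gap - 2L * min_gap
    u <- sort(stats::runif(n_sites, 0, max(slack, 1)))
    start <- as.integer(floor(u)) + min_gap + (seq_len(n_sites) - 1L) * min_gap
  })
  data.frame(chrom = chrom, start = start, end = start + width,
             name = sprintf("site_%04d", seq_len(n_sites)),
             score = 0, strand = ".", summit_offset = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Simulate nucleosomal fragments under a scenario
#'
#' For each site, occupied with probability `bound_fraction`: phased dyads at
#' `center +/- (plus_one_distance/2 + k * nrl)`, `k = 0..n_per_side-1`, each
#' jittered by `N(0, (jitter_sd0 + k * jitter_growth)^2)` and sampled
#' `Poisson(dyads_per_site / (2 * n_per_side))` times. Unoccupied sites get
#' `Poisson(dyads_per_site)` dyads at the site center (nucleosome occupancy
#' of vacant sequences). Background dyads arrive as a Poisson process at
#' `background_rate` per bp across each site window. Each dyad becomes a
#' fragment `[dyad - floor(core/2) - L_left, dyad + ceil(core/2) + L_right)`
#' with geometric overhangs of mean `overhang_mean`, so the fragment midpoint
#' recovers the dyad exactly when the overhangs are symmetric.
#'
#' @param sites Site table.
#' @param spec A [scenario_spec()]; its `seed` drives all randomness.
#' @param window_bp Half-width of the per-site window that receives
#'   background dyads (bp).
#' @return Fragment table (`chrom`, `start`, `end`); attribute `n_clipped`
#'   counts fragments clipped at coordinate 0.
#' @export
simulate_fragments <- function(sites, spec, window_bp = 1200L) {
  stopifnot(nrow(sites) >= 1, inherits(spec, "scenario_spec"))
  a <- spec$array
  d <- spec$digestion
  centers <- interval_center(sites$start, sites$end)
  n <- length(centers)
  withr::with_seed(spec$seed, {
    bound <- stats::runif(n) < a$bound_fraction
    dyad_pos <- integer(0)
    dyad_chrom <- character(0)
    # phased arrays at bound sites
    if (any(bound)) {
      nb <- sum(bound)
      k <- rep(seq_len(a$n_per_side) - 1L, times = 2L)       # per side
      side <- rep(c(-1L, 1L), each = a$n_per_side)
      lam <- d$dyads_per_site / (2 * a$n_per_side)
      grid_mu <- side * (a$plus_one_distance / 2 + k * a$nrl)
      grid_sd <- a$jitter_sd0 + k * a$jitter_growth
      cnt <- stats::rpois(nb * length(grid_mu), lam)
      mu <- rep(rep(centers[bound], each = length(grid_mu)) + grid_mu, cnt)
      sd <- rep(rep(grid_sd, nb), cnt)
      ch <- rep(rep(sites$chrom[bound], each = length(grid_mu)), cnt)
      pos <- as.integer(round(mu + stats::rnorm(length(mu), 0, sd)))
      dyad_pos <- c(dyad_pos, pos)
      dyad_chrom <- c(dyad_chrom, ch)
    }
    # site-centered nucleosome at unbound sites
    if (any(!bound)) {
      cnt <- stats::rpois(sum(!bound), d$dyads_per_site)
      mu <- rep(centers[!bound], cnt)
      ch <- rep(sites$chrom[!bound], cnt)
      pos <- as.integer(round(mu + stats::rnorm(length(mu), 0, a$jitter_sd0)))
      dyad_pos <- c(dyad_pos, pos)
      dyad_chrom <- c(dyad_chrom, ch)
    }
    # uniform background across each site window
    if (a$background_rate > 0) {
      w <- 2L * window_bp + 1L
      cnt <- stats::rpois(n, a$background_rate * w)
      lo <- rep(centers - window_bp, cnt)
      ch <- rep(sites$chrom, cnt)
      pos <- as.integer(lo + floor(stats::runif(length(lo), 0, w)))
      dyad_pos <- c(dyad_pos, pos)
      dyad_chrom <- c(dyad_chrom, ch)
    }
    frags <- dyads_to_fragments(dyad_chrom, dyad_pos, d$core_bp, d$overhang_mean)
  })
  frags
}

# Convert dyad positions to fragments with geometric linker overhangs.
# Called inside an already-seeded context.
dyads_to_fragments <- function(chrom, dyad, core_bp, overhang_mean) {
  m <- length(dyad)
  if (overhang_mean > 0) {
    p <- 1 / (1 + overhang_mean)
    l_left <- stats::rgeom(m, p)
    l_right <- stats::rgeom(m, p)
  } else {
    l_left <- l_right <- integer(m)
  }
  half <- core_bp %/% 2L
  start <- dyad - half - l_left
  end <- dyad + (core_bp - half) + l_right
  clipped <- start < 0L
  start[clipped] <- 0L
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Simulate ChIP fragments with per-site enrichment
#'
#' Fragment midpoints are drawn from a mixture of per-site Gaussians (weight
#' proportional to `enrichment - 1` above a uniform background over the site
#' windows), emulating factor ChIP peaks at bound sites.
#'
#' @param sites Site table.
#' @param enrichment Fold enrichment over background at site centers
#'   (must be at least 1; 1 = no enrichment).
#' @param peak_sd Gaussian s.d. of the ChIP peak (bp).
#' @param n_fragments Total fragments to draw.
#' @param frag_len_mean Mean fragment length (bp).
#' @param seed Integer seed.
#' @param window_bp Half-width of the per-site background window (bp).
#' @return Fragment table (`chrom`, `start`, `end`).
#' @export
simulate_chip_fragments <- function(sites, enrichment = 10, peak_sd = 100,
                                    n_fragments = 1e5, frag_len_mean = 200,
                                    seed = 1L, window_bp = 1000L) {
  stopifnot(enrichment >= 1, nrow(sites) >= 1)
  centers <- interval_center(sites$start, sites$end)
  n <- length(centers)
  w <- 2L * window_bp + 1L
  # mixture weight chosen so total density at a site center is `enrichment`
  # times the uniform background density: p/(1-p) = (E-1) * sqrt(2*pi)*sd / w
  odds <- (enrichment - 1) * sqrt(2 * pi) * peak_sd / w
  p_peak <- odds / (1 + odds)
  withr::with_seed(seed, {
    site_idx <- sample.int(n, n_fragments, replace = TRUE)
    from_peak <- stats::runif(n_fragments) < p_peak
    mid <- numeric(n_fragments)
    mid[from_peak] <- centers[site_idx[from_peak]] +
      stats::rnorm(sum(from_peak), 0, peak_sd)
    mid[!from_peak] <- centers[site_idx[!from_peak]] +
      stats::runif(sum(!from_peak), -window_bp, window_bp)
    mid <- as.integer(round(mid))
    len <- pmax(50L, as.integer(round(stats::rnorm(n_fragments, frag_len_mean,
                                                   frag_len_mean / 10))))
    start <- pmax(0L, mid - len %/% 2L)
    out <- data.frame(chrom = sites$chrom[site_idx], start = start,
                      end = start + len, stringsAsFactors = FALSE)
  })
  out
}

#' Simulate a pair of differential-expression tables
#'
#' Builds two tables over a shared gene universe: `n_shared` genes carry
#' correlated true effects (bivariate normal log2 fold changes with
#' correlation `rho_target`), `n_private_a`/`n_private_b` genes carry
#' independent effects in one table each, and the remainder are null. Every
#' gene's observed log2 fold change is its true effect plus `N(0, se)`
#' measurement noise, the p-value is the two-sided normal test of that
#' observation, and q-values are Benjamini-Hochberg within each table.
#'
#' @param n_genes Universe size.
#' @param n_shared Genes with correlated effects in both tables.
#' @param n_private_a,n_private_b Genes with an effect in one table only,
#'   drawn independently (they may overlap each other by chance, which is
#'   exactly the null for overlap testing).
#' @param effect_log2fc_sd S.d. of true effect log2 fold changes.
#' @param rho_target Correlation of the shared true effects.
#' @param se Per-gene measurement s.e. on the log2 scale.
#' @param seed Integer seed.
#' @return List with DE tables `a` and `b` ([read_de_table()] layout).
#' @export
simulate_de_tables <- function(n_genes, n_shared, n_private_a, n_private_b,
                               effect_log2fc_sd = 1.5, rho_target = 0.85,
                               se = 0.15, seed = 1L) {
  if (n_shared + n_private_a > n_genes || n_shared + n_private_b > n_genes) {
    stop("effect gene counts exceed the gene universe", call. = FALSE)
  }
  ids <- sprintf("g%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    shared <- sample(ids, n_shared)
    pool <- setdiff(ids, shared)
    priv_a <- sample(pool, n_private_a)
    priv_b <- sample(pool, n_private_b)
    la <- lb <- stats::setNames(numeric(n_genes), ids)
    if (n_shared > 0) {
      z1 <- stats::rnorm(n_shared)
      z2 <- rho_target * z1 + sqrt(max(0, 1 - rho_target^2)) * stats::rnorm(n_shared)
      la[shared] <- effect_log2fc_sd * z1
      lb[shared] <- effect_log2fc_sd * z2
    }
    la[priv_a] <- stats::rnorm(n_private_a, 0, effect_log2fc_sd)
    lb[priv_b] <- stats::rnorm(n_private_b, 0, effect_log2fc_sd)
    make_tab <- function(l_true) {
      obs <- l_true + stats::rnorm(n_genes, 0, se)
      p <- 2 * stats::pnorm(-abs(obs) / se)
      data.frame(gene_id = ids, fold_change = 2^obs, p_value = p,
                 q_value = stats::p.adjust(p, method = "BH"),
                 stringsAsFactors = FALSE)
    }
    out <- list(a = make_tab(la), b = make_tab(lb))
  })
  out
}

# center of a 0-based half-open interval
interval_center <- function(start, end) {
  as.integer(start + (end - start) %/% 2L)
}
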