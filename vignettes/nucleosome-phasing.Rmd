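---
title: "Quantifying nucleosome phasing around transcription-factor binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome phasing around transcription-factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Stably bound architectural factors such as CTCF act as barriers against
which ATP-dependent remodelling enzymes (the ISWI-family ATPases SNF2H and
SNF2L in human cells) pack regularly spaced nucleosomes. Individual loci are
sequenced far too sparsely to call single nucleosome positions, so the
field's standard readout is the *metaprofile*: paired-end MNase-seq
fragments are reduced to their midpoints (a proxy for the nucleosome dyad),
midpoints are counted per base in a window centered on many aligned binding
sites, and the averaged profile shows phasing as a decaying oscillation on
each flank.

`nucphasing` implements that computation end to end and the statistics
derived from it:

* **Digestion matching.** MNase digestion extent shifts the apparent
  nucleosome distribution; the mean fragment length measures it (147 bp at
  complete digestion down to the protected core, longer when linker
  overhangs survive). Two samples are comparable only when their mean
  lengths agree within 5 bp (inclusive); `digestion_match()` enforces this
  and `run_pipeline()` flags failing pairs `not_comparable`.
* **Proximity filtering.** Many factors have a CTCF site within 500 bp, and
  CTCF's own arrays would be attributed to the factor. `filter_by_proximity()`
  excludes any site whose center lies within a configurable radius (500 bp
  default, inclusive) of a reference-site center on the same chromosome.
  The underlying data do not say whether peak edges or centers were
  compared originally; center-to-center is symmetric, summit-compatible,
  and one flag away from the alternative.
* **Profile construction.** `aggregate_dyads()` counts dyads per offset in a
  ±1000 bp window (2001 bases, both endpoints included). `normalize_profile()`
  divides by `n_sites × total_fragments` and then rescales the window to a
  common mean (1.0 by default), so libraries of different depth plot on one
  axis. `smooth_profile()` applies a centered 50 bp sliding window for
  presentation and peak detection; an even width is promoted to the next odd
  value (50 → 51) for symmetry — a sub-resolution change. At the window edges
  the box shrinks symmetrically rather than inventing data, and a final
  rescale restores the window mean exactly, preserving the equal-mean
  normalization to 1e-9.
* **Phasing metrics.** `detect_peaks()` finds local maxima, filters them by
  topographic prominence relative to the profile s.d. (invariant to the
  rescaling constant), refines each peak position to the baseline-subtracted
  centroid of its symmetric neighbourhood, and applies greedy non-maximum
  suppression with a 120 bp minimum separation — below the smallest
  plausible repeat (~147 bp core) yet above smoothing ripple. The centroid
  step matters: a box-smoothed narrow peak has a nearly flat top whose raw
  argmax wanders by ±20 bp with sampling noise, while the centroid recovers
  the dyad position to about a base pair. `summarize_phasing()` reports the
  +1/−1 peak positions and distance and estimates the nucleosome repeat
  length (NRL) per flank as the least-squares slope of peak distance on peak
  index, which tolerates one missed peak; the adjacent-difference mean is
  carried as a cross-check. Peaks within 73 bp of the anchor (half a core)
  are treated as the site-centered nucleosome of vacant sites, not as
  array peaks.
* **Occupancy change.** For ChIP profiles, `occupancy_change()` measures
  enrichment as (central-band mean − background)/background with the
  background taken from the outermost 10% of the window on each side. The
  ratio form makes the statistic invariant to the mean-rescaling constant,
  so the percent reduction between conditions reflects only the loss of
  enrichment above background.
* **Co-regulation.** `filter_significant()` applies the strict
  >1.5-fold, p < 0.05, q < 0.05 gates; `overlap_test()` computes the
  one-sided (enrichment) hypergeometric tail by log-space summation, exact
  far below double underflow (observed overlaps reach p < 1e-100);
  `concordance()` computes Spearman's rank correlation of signed log2 fold
  changes with average ranks and the large-sample t approximation.

## The synthetic generator and what it emulates

`simulate_fragments()` embodies the barrier model directly: for each bound
site (probability `bound_fraction`, default 0.95) dyads are placed at
±(`plus_one_distance`/2 + k·`nrl`) for k = 0..`n_per_side`−1, each
perturbed by Gaussian noise of s.d. `jitter_sd0 + k·jitter_growth`. The
linear jitter growth reproduces the observed decay of phasing away from the
barrier with one parameter. Unbound sites receive a site-centered
nucleosome, reproducing the occupancy gain at vacant sites after barrier
loss. A uniform Poisson background adds unphased dyads. Each dyad becomes a
fragment of the 147 bp core plus independent geometric linker overhangs —
the simplest one-parameter family whose mean (`147 + 2·overhang_mean`)
can be pointed at any digestion level (0 → 147 bp, 11 → 169 bp).

The preset scenarios encode the study conditions: control arrays at 176 bp
repeat (the CTCF-adjacent spacing; 198 bp reproduces the genome-wide
mammalian value); SNF2H depletion widens the repeat to 183 bp and the +1/−1
distance by 25 bp with faster jitter growth; SNF2L depletion narrows them to
173 bp and −10 bp; CTCF depletion drops `bound_fraction` to 0.3. Two
parameters are the package's own calibrations because no measured value
exists for them: the control +1/−1 distance (280 bp, mid-range of the
258–364 bp survey across factors) and the jitter scales (2 bp initial s.d.,
1 bp/index growth; 3 bp/index for SNF2H depletion). The DE generator gives
every gene an observed log2 fold change equal to its true effect plus
N(0, se) noise and the corresponding two-sided normal p-value, with
Benjamini–Hochberg q-values per table; shared genes draw correlated
bivariate-normal true effects. This is a minimal significance model — one
mechanism produces effects, nulls, p and q coherently — not a model of
count noise.

What the generator does *not* emulate: sequence-dependent nucleosome
affinity, mappability and GC bias, chromosome-scale genomes, cohesin loops,
and MNase sequence preference. Passing tests therefore demonstrate that the
pipeline recovers the parameters of data with this statistical structure;
they do not validate the barrier model itself against real chromatin.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open throughout (BED convention); interval
centers and fragment midpoints use the floored half-width so every position
is deterministic. BEDPE mates merge to their outer span; over-length and
inter-chromosomal pairs are dropped and counted, never fatal, mirroring the
aligner's insert cap (500 bp nucleosomal, 1500 bp ChIP). All-zero profiles
refuse to normalize ("no signal in window"); flat profiles yield an empty
peak set; a flank with fewer than two peaks gets no NRL, and a summary with
neither flank is an error. Peak ties at equal prominence resolve toward the
smaller absolute offset. Every simulation consumes one seeded generator per
call, so a `scenario_spec` reproduces byte-identical data, and pipeline
manifests contain no timestamps so identical configs give identical output.

## Problem sizes

The bundled analysis scripts and tests run cohorts of 150–2000 sites with
~30 dyads per site (roughly 3–7 × 10⁴ fragments per cohort) and average 3–10
seeds per estimate; digestion statistics use 10⁵ fragments. At these sizes
the repeat length is recovered to well under 1 bp on average, so the ±2–3 bp
acceptance bands are dominated by model error, not sampling noise.

## Limitations

The NRL estimator assumes approximately equidistant peaks per flank; arrays
with position-dependent spacing would bias the slope. The proximity filter
compares centers, not edges, and the spacing survey averages flanks with
equal weight — both are documented choices where the original analysis is
ambiguous. Real-data p-values and percentage occupancy changes depend on
read depth and antibody efficiency that the ChIP generator only sketches;
its role is to verify the measurement code, not to predict effect sizes.
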