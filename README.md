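# nucphasing

Nucleosome phasing analysis around transcription-factor binding sites, as an
R package plus a scripted analysis workflow.

## The scientific problem

Stably bound factors such as CTCF act as barriers against which ISWI-family
chromatin remodelling enzymes (SNF2H, SNF2L) organise regularly spaced
nucleosome arrays. Sequencing depth forbids calling nucleosomes at single
loci, so positioning is measured on *metaprofiles*: paired-end MNase-seq
fragments are reduced to midpoints (dyad proxies) and counted per base in a
±1 kb window across thousands of aligned binding sites. Phasing appears as a
decaying oscillation on each flank; its period is the nucleosome repeat
length (NRL), and the distance between the first peaks on either side is the
+1/−1 distance set by the barrier.

For a profile built from dyads $m$ around site anchors $a_s$,

$$c(o) = \sum_s \#\{m : m - a_s = o\},\qquad
  v(o) = \alpha\,\frac{c(o)}{N_{\text{sites}}\,N_{\text{frags}}},\ |o|\le 1000,$$

with $\alpha$ chosen so the window mean of $v$ is common across conditions,
then smoothed with a centered 50 bp sliding window. Peaks are local maxima
filtered by prominence and refined to local centroids; per flank the NRL is
the least-squares slope of peak distance on peak index. Supporting
statistics: mean-fragment-length digestion matching (comparable iff within
5 bp), a 500 bp CTCF-proximity site filter, background-relative ChIP
occupancy change, and co-regulation tests on two differential-expression
tables (>1.5-fold, p < 0.05, q < 0.05 gates; one-sided hypergeometric
overlap computed in log space; Spearman concordance of log2 fold changes).

A synthetic phased-chromatin generator (barrier-model arrays with
configurable repeat length, jitter growth, digestion overhangs, depletion
scenario presets, ChIP enrichment, and paired DE tables) makes every stage
runnable and testable without any external data.

## Worked example

```r
library(nucphasing)

spec <- scenario_presets(seed = 42)$control     # 176 bp repeat, 280 bp +1/-1
res  <- run_scenario_cohort(spec, n_sites = 2000)
res$length_stats
#> Fragment length stats: n=69562 mean=147.00 bp mode=147 bp
res$summary
#> Phasing: +1 at 140.0, -1 at -139.7, +1/-1 distance 279.7 bp, NRL 176.0 bp (L 176.2 / R 175.9)
round(res$peaks$peak_offsets, 1)
#>  [1] -844.1 -668.2 -492.0 -315.3 -139.7   -0.3  140.0  316.1  492.2  667.8  843.6
```

The mean fragment length of 147 bp confirms complete digestion to the
nucleosome core. The peak ladder sits on the generator's dyad lattice
(±140, ±316, … bp, the small peak near 0 being the occupancy of the few
unbound sites), and the per-flank regression recovers the 176 bp repeat and
280 bp +1/−1 distance to within a fraction of a base pair.

The numbered scripts under `analysis/` run the full study on simulated
cohorts — `01` generates data, `02` checks digestion matching, `03` builds
metaprofiles, `04` quantifies phasing and depletion deltas, `05` runs the
co-regulation analysis — writing tables under `results/`. From `04`:

```
       scenario n_peaks plus_one minus_one  p1m1    nrl delta_p1m1 delta_nrl
        control      11    139.8    -139.9 279.7 176.02        0.0      0.00
 snf2h_depleted      11    153.0    -152.3 305.3 183.04       25.6      7.01
 snf2l_depleted      11    134.8    -135.0 269.8 173.00       -9.9     -3.03
  ctcf_depleted       1       NA        NA    NA     NA         NA        NA
```

`run_pipeline(config, out_dir)` drives the same stages from a YAML/list
config over files or scenarios, writing profiles, summaries and a
deterministic `manifest.json`.

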