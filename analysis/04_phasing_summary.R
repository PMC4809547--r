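#!/usr/bin/env Rscript
# Phasing quantification per scenario: peak positions, +1/-1 distance, and
# per-flank regression NRL, plus deltas of each depletion against the
# control. This reproduces the spacing survey numbers on the synthetic
# cohorts.

suppressPackageStartupMessages(library(nucphasing))

prof_dir <- file.path("results", "profiles")
scenarios <- c("control", "snf2h_depleted", "snf2l_depleted", "ctcf_depleted")

runs <- lapply(scenarios, function(nm) {
  prof <- read_profile(file.path(prof_dir, paste0(nm, ".tsv")))
  peaks <- detect_peaks(prof)
  summ <- tryCatch(summarize_phasing(prof, peaks), error = function(e) NULL)
  list(name = nm, profile = prof, peaks = peaks, summary = summ)
})
names(runs) <- scenarios

rows <- lapply(runs, function(r) {
  s <- r$summary
  if (is.null(s)) {
    return(data.frame(scenario = r$name, n_peaks = length(r$peaks$peak_offsets),
                      plus_one = NA, minus_one = NA, p1m1 = NA, nrl = NA,
                      delta_p1m1 = NA, delta_nrl = NA))
  }
  d <- if (r$name == "control") list(delta_p1m1 = 0, delta_nrl = 0) else
    compare_conditions(runs$control, r)
  data.frame(scenario = r$name, n_peaks = length(r$peaks$peak_offsets),
             plus_one = round(s$plus_one, 1), minus_one = round(s$minus_one, 1),
             p1m1 = round(s$p1m1_distance, 1), nrl = round(s$nrl, 2),
             delta_p1m1 = round(d$delta_p1m1, 1),
             delta_nrl = round(d$delta_nrl, 2))
})
tab <- do.call(rbind, rows)
write.table(tab, file.path("results", "phasing_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
message("\nExpected from the generator settings: control NRL 176 bp;
SNF2H depletion -> NRL 183 (+7), +1/-1 +25 bp; SNF2L -> NRL 173 (-3),
+1/-1 -10 bp; CTCF depletion -> phasing largely lost, occupancy gained
at the site center.")
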