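#!/usr/bin/env Rscript
# Generate the synthetic study datasets: one cohort of factor binding sites
# per scenario preset with matching nucleosomal fragments, plus a pair of
# differential-expression tables with a shared-effect gene subset. Everything
# downstream (02-05) reads these files, so the whole analysis is
# reproducible from this script alone.

suppressPackageStartupMessages(library(nucphasing))

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seed <- 2026L
n_sites <- 1000L

sites <- simulate_sites(n_sites, chrom_length = (n_sites + 2L) * 5100L,
                        min_gap = 5000L, seed = seed)
write_sites(sites, file.path(out, "sites.bed"))
message(sprintf("sites: %d non-overlapping 19 bp sites on one synthetic chromosome",
                nrow(sites)))

for (nm in names(scenario_presets())) {
  spec <- scenario_presets(seed = seed)[[nm]]
  frags <- simulate_fragments(sites, spec)
  write_fragments(frags, file.path(out, paste0(nm, ".bedpe")))
  message(sprintf("%-15s %6d fragments (mean length %.1f bp)",
                  nm, nrow(frags), mean(frags$end - frags$start)))
}

# lightly digested control: same chromatin, incomplete MNase digestion
light <- scenario_spec("control", array_model(),
                       digestion_model(overhang_mean = 11), seed = seed)
write_fragments(simulate_fragments(sites, light),
                file.path(out, "control_light_digest.bedpe"))

# paired DE tables at the scale of the co-regulation experiment:
# 3294 measurable genes, ~1000 affected per depletion, strong shared subset
de <- simulate_de_tables(3294, n_shared = 700, n_private_a = 300,
                         n_private_b = 300, seed = seed)
write_de_table(de$a, file.path(out, "de_ctcf_depletion.tsv"))
write_de_table(de$b, file.path(out, "de_snf2h_depletion.tsv"))
message("DE tables: 3294-gene universe, 700 shared + 300 private effects each")
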