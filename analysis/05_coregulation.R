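#!/usr/bin/env Rscript
# Co-regulation analysis of the paired depletion DE tables: significance
# filtering (>1.5-fold, p < 0.05, q < 0.05), hypergeometric overlap of the
# two affected gene sets, and Spearman concordance of their fold changes.

suppressPackageStartupMessages(library(nucphasing))

data_dir <- file.path("results", "data")
ta <- read_de_table(file.path(data_dir, "de_ctcf_depletion.tsv"))
tb <- read_de_table(file.path(data_dir, "de_snf2h_depletion.tsv"))

res <- coregulation_analysis(ta, tb)
print(res)
message(sprintf("Spearman rho over the %d shared genes: %.3f (p = %.3g)",
                res$n_shared, res$spearman_rho, res$spearman_p))

jsonlite::write_json(unclass(res), file.path("results", "coregulation.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
message("wrote results/coregulation.json")
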