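Package: nucphasing
Title: Nucleosome Phasing Analysis Around Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dyad metaprofile analysis of MNase-seq nucleosome positioning
    around transcription-factor binding sites. Converts paired-end fragments
    to dyad (midpoint) positions, aggregates per-base dyad density in a
    window centered on aligned binding sites, applies depth/site-count
    normalization and sliding-window smoothing, detects phased nucleosome
    peaks, and estimates the +1/-1 inter-nucleosome distance and the
    nucleosome repeat length per flank by regression. Includes
    digestion-extent matching of samples by mean fragment length, a
    CTCF-proximity site filter, ChIP occupancy-change quantification,
    gene-set overlap statistics for co-regulation analysis, and a synthetic
    phased-chromatin generator (barrier-model nucleosome arrays with
    configurable repeat length, jitter, digestion overhangs, and depletion
    scenario presets) so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
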