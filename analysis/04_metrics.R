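#!/usr/bin/env Rscript

# 04: Library-level metrics.
#
# Computes the summary panel over the classified junctions -- V-J efficiency,
# CE/SE usage, the 41-bin structure distribution with the MMEJ fraction,
# resection enrichment, sub-TAD usage, and relative/absolute translocation
# frequencies -- and writes the metric tables.

suppressPackageStartupMessages(library(baitjoin))

outdir <- "results/baseline"
spec <- load_locus_spec(file.path(outdir, "locus.bed"),
                        file.path(outdir, "locus.yaml"))
classified <- utils::read.delim(file.path(outdir, "classified.tsv"))

config <- sim_config(n_read_pairs = 50000L, seed = 1L)
metrics <- compute_metrics(classified, spec, config$n_read_pairs)
print(metrics)

write_metrics(metrics, file.path(outdir, "metrics"))
cat("wrote", file.path(outdir, "metrics_summary.tsv"), "\n")
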