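#!/usr/bin/env Rscript

# 03: Classify the called junctions.
#
# Annotates every junction with its joint structure (microhomology / direct /
# insertion, palindromy), positional category (V-J, rejoin, intra-locus,
# translocation), prey end type and configuration, resection offset from the
# assigned cut site, and sub-TAD.

suppressPackageStartupMessages(library(baitjoin))

outdir <- "results/baseline"
spec <- load_locus_spec(file.path(outdir, "locus.bed"),
                        file.path(outdir, "locus.yaml"))
tlx <- read_tlx(file.path(outdir, "junctions.tlx"))

classified <- classify_junctions(tlx, spec, "J1CE")

utils::write.table(classified, file.path(outdir, "classified.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("categories:\n")
print(table(classified$category))
cat("\nV-region joint structure:\n")
v <- classified[classified$category == "V_J", ]
print(table(v$structure_kind, v$structure_length))

cat("\nwrote", file.path(outdir, "classified.tsv"), "\n")
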