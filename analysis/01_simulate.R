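#!/usr/bin/env Rscript

# 01: Simulate the baseline library.
#
# Builds the guarded toy genome for the default antigen-receptor locus and
# simulates one alternative-end-joining library from the coding-end bait,
# writing the genome, reads, and ground truth under results/baseline/.

suppressPackageStartupMessages(library(baitjoin))

outdir <- "results/baseline"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

spec <- default_locus_spec()
genome <- build_toy_genome(spec, seed = 100L)
config <- sim_config(n_read_pairs = 50000L, seed = 1L)

sim <- simulate_library(config, spec, genome)
print(sim)

write_genome_fasta(genome, file.path(outdir, "genome.fa"))
write_library(sim, file.path(outdir, "reads.fastq"),
              file.path(outdir, "truth.tsv"))
write_locus_spec(spec, file.path(outdir, "locus.bed"),
                 file.path(outdir, "locus.yaml"))

cat("wrote", outdir, "\n")
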