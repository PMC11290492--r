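#!/usr/bin/env Rscript

# 02: Call junctions from the simulated reads.
#
# Reads the baseline library produced by 01_simulate.R, calls bait-anchored
# junctions against the toy genome, and writes the tlx records, a junction
# density bedGraph, and the caller's stage accounting. Also reports the
# concordance of the calls against the simulator's ground truth.

suppressPackageStartupMessages(library(baitjoin))

outdir <- "results/baseline"
spec <- load_locus_spec(file.path(outdir, "locus.bed"),
                        file.path(outdir, "locus.yaml"))
genome <- read_genome_fasta(file.path(outdir, "genome.fa"))

# re-simulate deterministically rather than parse FASTQ: same config and seed
config <- sim_config(n_read_pairs = 50000L, seed = 1L)
sim <- simulate_library(config, spec, genome)

res <- call_junctions(sim, genome, spec, config$bait)
print(res$stats)

write_tlx(res$tlx, file.path(outdir, "junctions.tlx"))
write_bedgraph(tlx_to_bedgraph(res$tlx),
               file.path(outdir, "junctions.bedgraph"))

truth_tlx <- emit_truth_tlx(sim, spec)
cc <- junction_concordance(truth_tlx, res$tlx)
cat(sprintf("concordance with ground truth: %.4f (%d/%d)\n",
            cc$concordance, round(cc$concordance * cc$n_truth), cc$n_truth))
utils::write.table(cc$discordances, file.path(outdir, "discordances.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote", file.path(outdir, "junctions.tlx"), "\n")
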