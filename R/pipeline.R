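#' Run the full simulate-call-classify-measure pipeline
#'
#' Builds the toy genome, simulates the library, calls junctions from the
#' reads (or converts the ground truth directly to tlx when
#' `use_truth = TRUE`), classifies them, computes the metrics panel and, when
#' `outdir` is given, writes every artefact plus a manifest with MD5 checksums.
#' Fully deterministic: the same config, spec and genome seed produce
#' byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @param spec a `locus_spec` (default [default_locus_spec()]).
#' @param outdir output directory, created if needed; `NULL` skips writing.
#' @param genome_seed seed for [build_toy_genome()] (default 100).
#' @param flank_guard passed to [build_toy_genome()].
#' @param use_truth bypass the read-level caller and classify the
#'   ground-truth tlx instead (for caller-independent testing).
#' @return list with `genome`, `sim`, `tlx`, `classified`, `metrics`,
#'   `caller_stats` (`NULL` when `use_truth`), `manifest`.
#' @export
run_pipeline <- function(config, spec = default_locus_spec(), outdir = NULL,
                         genome_seed = 100L, flank_guard = "on",
                         use_truth = FALSE) {
  genome <- build_toy_genome(spec, seed = genome_seed,
                             flank_guard = flank_guard)
  sim <- simulate_library(config, spec, genome)
  if (use_truth) {
    tlx <- emit_truth_tlx(sim, spec)
    caller_stats <- NULL
  } else {
    called <- call_junctions(sim$reads, genome, spec, config$bait)
    tlx <- called$tlx
    caller_stats <- called$stats
  }
  classified <- classify_junctions(tlx, spec, config$bait)
  metrics <- compute_metrics(classified, spec, nrow(sim$reads))

  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_genome_fasta(genome, p("genome.fa"))
    write_library(sim, p("reads.fastq"), p("truth.tsv"))
    write_tlx(tlx, p("junctions.tlx"))
    utils::write.table(classified, p("classified.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bedgraph(tlx_to_bedgraph(tlx), p("junctions.bedgraph"))
    write_metrics(metrics, p("metrics"))
    files <- c("genome.fa", "reads.fastq", "truth.tsv", "junctions.tlx",
               "classified.tsv", "junctions.bedgraph", "metrics_summary.tsv",
               "metrics_structure.tsv", "metrics_stads.tsv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("baitjoin")),
      genome_seed = genome_seed,
      flank_guard = flank_guard,
      use_truth = use_truth,
      config = unclass(config),
      checksums = as.list(tools::md5sum(file.path(outdir, files)))
    )
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  list(genome = genome, sim = sim, tlx = tlx, classified = classified,
       metrics = metrics, caller_stats = caller_stats, manifest = manifest)
}
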