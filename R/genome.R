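#' Build the toy reference genome for a locus specification
#'
#' Generates random chromosome sequences of the lengths declared in the spec.
#' With `flank_guard = "on"` (the default) the bases flanking every RAG1/2
#' scission point are re-drawn so that, for every bait/V-flank pair, no chance
#' bait-suffix/prey-prefix identity of length >= 1 exists at the zero-resection
#' junction: a direct joint written at the cut sites is then recovered as a
#' direct joint, and intended microhomology cannot be lengthened by chance at
#' the cut. The repair is iterative; if a conflicting constraint set leaves a
#' flanking base with no admissible value the builder errors.
#'
#' @param spec a `locus_spec` (used as the coordinate template).
#' @param seed integer seed; the same seed yields a byte-identical genome.
#' @param flank_guard `"on"` or `"off"`.
#' @return a `toy_genome`: list with `seq` (named character vector of
#'   chromosome sequences) and `flank_guard`.
#' @export
build_toy_genome <- function(spec, seed = 1L, flank_guard = c("on", "off")) {
  flank_guard <- match.arg(flank_guard)
  genome <- with_seed(seed, {
    seqs <- vapply(spec$chrom_lengths, random_dna, "")
    names(seqs) <- names(spec$chrom_lengths)
    g <- structure(list(seq = as.list(seqs), flank_guard = flank_guard),
                   class = "toy_genome")
    if (flank_guard == "on") g <- apply_flank_guard(g, spec)
    g
  })
  genome
}

## The guarded flank pairs: each bait end against each V-segment flank
## (coding and signal). Rejoin flanks are excluded by construction: the distal
## flank of a bait's own DSB *is* the reference continuation, so a perfectly
## religated end is indistinguishable from unbroken DNA; junction-site
## enumeration handles rejoins at the realised resections instead.
guard_pairs <- function(spec) {
  pairs <- list()
  vseg <- spec$segments[spec$segments$role == "V", ]
  for (bi in seq_len(nrow(spec$baits))) {
    bg <- bait_geometry(spec$baits[bi, ])
    for (si in seq_len(nrow(vseg))) {
      for (et in c("CE", "SE")) {
        pairs[[length(pairs) + 1L]] <-
          list(bg = bg, pg = prey_geometry_v(vseg[si, ], et))
      }
    }
  }
  pairs
}

## Maximal suffix/prefix overlap (in bp, up to `kmax`) between the bait's
## retained flank and a prey flank at zero resection, plus the two single-base
## extension checks at a direct (0,0) junction. Used both by the guard repair
## and by the brute-force verification scan.
flank_pair_violations <- function(genome, bg, pg, kmax = 25L) {
  sb <- genome$seq[[bg$chrom]]
  sp <- genome$seq[[pg$chrom]]
  viol <- list()
  for (k in seq_len(kmax)) {
    if (bait_suffix(sb, bg, 0L, k) == prey_at_prefix(sp, pg, k)) {
      # suffix-k of the bait flank equals prefix-k of the prey flank: a direct
      # junction at resections (0, k) would read back as MH-k
      viol[[length(viol) + 1L]] <- list(
        kind = "overlap", k = k,
        pos = prey_jb(pg, 0L) + pg$dir * (k - 1L), chrom = pg$chrom,
        must_differ_from = as_genomic_base(bait_char_from_end(sb, bg, 0L, 1L),
                                           pg$dir))
    }
  }
  # prey-left extension at (0,0): last bait base vs base upstream of prey cut
  if (bait_char_from_end(sb, bg, 0L, 1L) == prey_before_char(sp, pg, 0L, 1L)) {
    viol[[length(viol) + 1L]] <- list(
      kind = "left_block", k = 0L,
      pos = prey_jb(pg, 0L) - pg$dir, chrom = pg$chrom,
      must_differ_from = as_genomic_base(bait_char_from_end(sb, bg, 0L, 1L),
                                         pg$dir))
  }
  # bait-right extension at (0,0): bait continuation vs first prey base
  if (bait_next_char(sb, bg, 0L) == prey_at_char(sp, pg, 0L)) {
    viol[[length(viol) + 1L]] <- list(
      kind = "right_block", k = 0L,
      pos = prey_jb(pg, 0L), chrom = pg$chrom,
      must_differ_from = as_genomic_base(bait_next_char(sb, bg, 0L), pg$dir))
  }
  viol
}

## first k bases of the prey's retained flank, as sequenced
prey_at_prefix <- function(chrom_seq, pg, k) {
  seq_fwd(chrom_seq, prey_jb(pg, 0L), k, pg$dir)
}

## convert an as-sequenced character back to genome (+ strand) space
as_genomic_base <- function(ch, dir) if (dir > 0) ch else comp_base(ch)

apply_flank_guard <- function(genome, spec, max_iter = 500L) {
  # When two baits flank the same DSB (coding- and signal-end libraries), the
  # two prey bases adjacent to each V cut site collect "must differ" blocks
  # from both bait-end bases *and* their complements -- four constraints that
  # are jointly satisfiable only if the two break-adjacent bait bases are
  # complementary. Pin them before the repair sweep.
  b <- spec$baits
  for (i in seq_len(nrow(b))) {
    for (j in seq_len(nrow(b))) {
      if (i < j && b$chrom[i] == b$chrom[j] &&
          abs(b$dsb_coordinate[i] - b$dsb_coordinate[j]) == 1L) {
        s <- genome$seq[[b$chrom[i]]]
        genome$seq[[b$chrom[i]]] <- set_base(
          s, b$dsb_coordinate[j],
          comp_base(get_base(s, b$dsb_coordinate[i])))
      }
    }
  }
  pairs <- guard_pairs(spec)
  for (iter in seq_len(max_iter)) {
    fixed_any <- FALSE
    for (p in pairs) {
      viol <- flank_pair_violations(genome, p$bg, p$pg)
      if (length(viol) == 0) next
      v <- viol[[1]]
      s <- genome$seq[[v$chrom]]
      current <- get_base(s, v$pos)
      allowed <- setdiff(DNA_BASES, c(current, v$must_differ_from))
      if (length(allowed) == 0) {
        stop("flank guard construction infeasible at ", v$chrom, ":", v$pos,
             call. = FALSE)
      }
      genome$seq[[v$chrom]] <- set_base(s, v$pos, sample(allowed, 1L))
      fixed_any <- TRUE
    }
    if (!fixed_any) return(genome)
  }
  stop("flank guard construction did not converge; segment density too high",
       call. = FALSE)
}

#' Write a toy genome as FASTA
#'
#' @param genome a `toy_genome`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  ss <- Biostrings::DNAStringSet(unlist(genome$seq))
  Biostrings::writeXStringSet(ss, file, width = 80L)
  invisible(file)
}

#' Read a toy genome from FASTA
#'
#' @param file FASTA path.
#' @return a `toy_genome`.
#' @export
read_genome_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  names(ss) <- sub("\\s.*$", "", names(ss))
  structure(list(seq = as.list(as.character(ss)), flank_guard = "unknown"),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", length(x$seq), " chromosomes (",
      paste0(names(x$seq), ":", vapply(x$seq, nchar, 1L), collapse = ", "),
      "), flank_guard=", x$flank_guard, "\n", sep = "")
  invisible(x)
}
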