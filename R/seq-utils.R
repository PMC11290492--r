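#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement quality BStringSet
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Character-native implementation (complement via [chartr()], reversal via
#' code-point vectors); far cheaper than round-tripping short strings through
#' XStringSet objects, which the simulator and caller do millions of times.
#'
#' @param x character vector of DNA sequences (ACGT alphabet).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Strand-aware sequence extraction
#'
#' Returns the sequence read starting at 0-based position `pos` and moving in
#' direction `dir` (+1 rightward on the reference, -1 leftward), reported in
#' read orientation (i.e. reverse-complemented when `dir == -1`).
#'
#' @param chrom_seq character scalar, the full chromosome sequence.
#' @param pos 0-based position of the first base.
#' @param len number of bases.
#' @param dir +1 or -1.
#' @return character scalar of length `len`.
#' @keywords internal
seq_fwd <- function(chrom_seq, pos, len, dir) {
  if (len <= 0) return("")
  if (dir > 0) {
    substr(chrom_seq, pos + 1L, pos + len)
  } else {
    revcomp(substr(chrom_seq, pos - len + 2L, pos + 1L))
  }
}

## Vectorised over pos; len scalar.
seq_fwd_vec <- function(chrom_seq, pos, len, dir) {
  if (len <= 0) return(rep("", length(pos)))
  if (dir > 0) {
    substring(chrom_seq, pos + 1L, pos + len)
  } else {
    revcomp(substring(chrom_seq, pos - len + 2L, pos + 1L))
  }
}

#' Positions at which two equal-length strings disagree
#' @keywords internal
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  which(ra[seq_len(n)] != rb[seq_len(n)])
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Replace the single base at 0-based position `pos`.
set_base <- function(chrom_seq, pos, base) {
  substr(chrom_seq, pos + 1L, pos + 1L) <- base
  chrom_seq
}

get_base <- function(chrom_seq, pos) substr(chrom_seq, pos + 1L, pos + 1L)

## Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
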