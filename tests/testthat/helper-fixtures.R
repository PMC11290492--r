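# Shared fixtures: a compact locus spec for fast unit tests, cached genomes,
# and an independent brute-force oracle for joint structure.

small_locus_spec <- function() {
  segments <- data.frame(
    name = c("V1", "V2", "V3", "V4", "J1"),
    chrom = "chrA",
    start = c(1500L, 2200L, 3500L, 4200L, 6000L),
    end = c(1700L, 2400L, 3700L, 4400L, 6200L),
    strand = c("+", "-", "+", "-", "+"),
    role = c("V", "V", "V", "V", "J"),
    configuration = c("DEL", "INV", "DEL", "INV", NA),
    cut_site = c(1699L, 2200L, 3699L, 4200L, 6000L),
    rss_side = c("right", "left", "right", "left", "left"),
    stringsAsFactors = FALSE
  )
  baits <- data.frame(
    name = c("BCE", "BSE"),
    side = c("CE", "SE"),
    chrom = "chrA",
    dsb_coordinate = c(6000L, 5999L),
    bait_strand = c("-", "+"),
    primer_start = c(6040L, 5940L),
    primer_end = c(6060L, 5960L),
    region_start = 5850L,
    region_end = 6150L,
    stringsAsFactors = FALSE
  )
  stads <- data.frame(label = c("s1", "s2"), chrom = "chrA",
                      start = c(1000L, 3000L), end = c(3000L, 5000L),
                      stringsAsFactors = FALSE)
  receptor_loci <- data.frame(label = "recX", chrom = "chrX",
                              start = 2000L, end = 2300L,
                              stringsAsFactors = FALSE)
  baitjoin:::new_locus_spec(
    segments = segments, baits = baits, stads = stads,
    locus = list(chrom = "chrA", start = 500L, end = 7000L),
    receptor_loci = receptor_loci,
    chrom_lengths = c(chrA = 12000L, chrX = 6000L, chrB = 6000L)
  )
}

small_config <- function(...) {
  sim_config(bait = "BCE", v_usage = c(s1 = 0.5, s2 = 0.5), ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_genome <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- build_toy_genome(small_locus_spec(), seed = 11)
  }
  .fixture_env$small
}

big_genome <- function() {
  if (is.null(.fixture_env$big)) {
    .fixture_env$big <- build_toy_genome(default_locus_spec(), seed = 100)
  }
  .fixture_env$big
}

# Independent brute-force structure oracle. Recovers the bait/prey alignment
# endpoints by direct character comparison against the reference strings
# (never reading B_Qend/Qstart) and classifies the junction from them.
oracle_structure <- function(rec, genome, bg) {
  n <- nchar(rec$Seq)
  sb <- genome$seq[[bg$chrom]]
  bait_path <- baitjoin:::seq_fwd(sb, bg$primer_outer, n, bg$dir)
  mmb <- baitjoin:::mismatch_positions(rec$Seq, bait_path)
  b_max <- if (length(mmb) == 0) n else mmb[1] - 1L
  dirp <- if (rec$Strand == "+") 1L else -1L
  sp <- genome$seq[[rec$Rname]]
  ref_end0 <- if (dirp > 0) rec$Rend - 1L else rec$Rstart - 1L
  t <- rec$Qend + 1L
  repeat {
    j <- t - 1L
    if (j < 1L) break
    ref0 <- ref_end0 - dirp * (rec$Qend - j)
    if (ref0 < 0L || ref0 >= nchar(sp)) break
    ch <- baitjoin:::seq_fwd(sp, ref0, 1L, dirp)
    if (ch != substr(rec$Seq, j, j)) break
    t <- j
  }
  p_min <- t
  o <- b_max - p_min + 1L
  if (o >= 1L) {
    list(kind = "MH", len = o, pal = FALSE)
  } else if (o == 0L) {
    list(kind = "direct", len = 0L, pal = FALSE)
  } else {
    m <- -o
    ins <- substr(rec$Seq, b_max + 1L, b_max + m)
    bait_flank <- substr(rec$Seq, b_max - m + 1L, b_max)
    prey_flank <- substr(rec$Seq, p_min, p_min + m - 1L)
    pal <- (nchar(bait_flank) == m &&
              ins == baitjoin:::revcomp(bait_flank)) ||
      (nchar(prey_flank) == m && ins == baitjoin:::revcomp(prey_flank))
    list(kind = "insertion", len = m, pal = pal)
  }
}
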