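## Junction geometry.
##
## Everything that touches a junction is expressed through two small geometry
## records so the simulator, the truth-table emitter and the tests share one
## coordinate convention:
##
##  * bait geometry: the read runs from the primer's outer end toward the DSB
##    (`dir` = +1 rightward / -1 leftward on the reference). `jb(r_b)` is the
##    0-based coordinate of the last sequenced bait base when `r_b` bases have
##    been resected from the break end.
##  * prey geometry: `anchor0` is the junction base at zero resection and the
##    prey portion of the read extends from `jb_p(r_p) = anchor0 + dir * r_p`
##    in direction `dir` (away from the break, into the retained flank).
##
## "As sequenced" strings returned by seq_fwd() are reverse-complemented when
## dir == -1, so string comparisons between bait and prey sides are always done
## in read orientation.

bait_geometry <- function(bait) {
  dir <- if (bait$bait_strand == "+") 1L else -1L
  primer_outer <- if (dir > 0) bait$primer_start else bait$primer_end - 1L
  list(
    name = bait$name,
    side = bait$side,
    chrom = bait$chrom,
    dir = dir,
    dsb = bait$dsb_coordinate,
    primer_outer = primer_outer,
    primer_len = bait$primer_end - bait$primer_start,
    region_start = bait$region_start,
    region_end = bait$region_end,
    # bases resected past this would remove the primer annealing site
    rb_headroom = abs(bait$dsb_coordinate - primer_outer) -
      (bait$primer_end - bait$primer_start) - 10L
  )
}

## last sequenced bait base after r_b bp of bait-side resection
bait_jb <- function(bg, r_b) bg$dsb - bg$dir * r_b

## length of the sequenced bait portion (primer through junction base)
bait_len <- function(bg, r_b) abs(bait_jb(bg, r_b) - bg$primer_outer) + 1L

## last k bait bases, as sequenced (vectorised over r_b)
bait_suffix <- function(chrom_seq, bg, r_b, k) {
  jb <- bait_jb(bg, r_b)
  seq_fwd_vec(chrom_seq, jb - bg$dir * (k - 1L), k, bg$dir)
}

## as-sequenced base `i` positions from the bait end (i = 1 is the last base)
bait_char_from_end <- function(chrom_seq, bg, r_b, i) {
  seq_fwd_vec(chrom_seq, bait_jb(bg, r_b) - bg$dir * (i - 1L), 1L, bg$dir)
}

## first reference base past the bait junction, in read orientation
bait_next_char <- function(chrom_seq, bg, r_b) {
  seq_fwd_vec(chrom_seq, bait_jb(bg, r_b) + bg$dir, 1L, bg$dir)
}

## Prey geometry for a V segment end, a rejoin (the distal flank of the bait
## DSB) or a translocation partner position.
prey_geometry_v <- function(segment, end_type) {
  cs <- segment$cut_site
  if (segment$strand == "+") {
    if (end_type == "CE") list(chrom = segment$chrom, anchor0 = cs, dir = -1L)
    else list(chrom = segment$chrom, anchor0 = cs + 1L, dir = 1L)
  } else {
    if (end_type == "CE") list(chrom = segment$chrom, anchor0 = cs, dir = 1L)
    else list(chrom = segment$chrom, anchor0 = cs - 1L, dir = -1L)
  }
}

prey_geometry_rejoin <- function(bg) {
  list(chrom = bg$chrom, anchor0 = bg$dsb + bg$dir, dir = bg$dir)
}

prey_geometry_point <- function(chrom, pos, dir) {
  list(chrom = chrom, anchor0 = as.integer(pos), dir = as.integer(dir))
}

prey_jb <- function(pg, r_p) pg$anchor0 + pg$dir * r_p

## k reference bases immediately upstream (read orientation) of the prey
## junction base -- the bases an MH-k junction shares with the bait suffix
prey_before <- function(chrom_seq, pg, r_p, k) {
  seq_fwd_vec(chrom_seq, prey_jb(pg, r_p) - pg$dir * k, k, pg$dir)
}

prey_before_char <- function(chrom_seq, pg, r_p, i) {
  seq_fwd_vec(chrom_seq, prey_jb(pg, r_p) - pg$dir * i, 1L, pg$dir)
}

## the prey junction base itself, as sequenced
prey_at_char <- function(chrom_seq, pg, r_p) {
  seq_fwd_vec(chrom_seq, prey_jb(pg, r_p), 1L, pg$dir)
}

## TRUE where every reference position touched by junction checks at
## (r_b, r_p, k) lies inside the chromosome
junction_in_bounds <- function(bg, pg, r_b, r_p, k, len_b, len_p) {
  jb <- bait_jb(bg, r_b)
  jp <- prey_jb(pg, r_p)
  bait_lo <- pmin(jb - bg$dir * k, jb + bg$dir)
  bait_hi <- pmax(jb - bg$dir * k, jb + bg$dir)
  prey_lo <- pmin(jp - pg$dir * (k + 1L), jp)
  prey_hi <- pmax(jp - pg$dir * (k + 1L), jp)
  bait_lo >= 0L & bait_hi < len_b & prey_lo >= 0L & prey_hi < len_p
}

#' Valid junction sites for one bait/prey flank pair
#'
#' Enumerates the (bait resection, prey resection) pairs at which a junction of
#' the requested structure can be written into a read such that the emergent
#' structure -- what a query-maximal aligner recovers -- equals the intended
#' one. For microhomology length `k >= 1` the k bases of the bait suffix must
#' equal the k reference bases immediately upstream of the prey junction, and
#' one-base mismatches must block any further extension on either frontier.
#' For a direct joint (`k = 0`) only the two blocking mismatches are required.
#'
#' @param genome a `toy_genome`.
#' @param bg,pg bait and prey geometry records.
#' @param k microhomology length (0 = direct joint).
#' @param rb_max,rp_max largest resections to consider.
#' @return data.frame with columns `r_b`, `r_p`.
#' @keywords internal
junction_sites <- function(genome, bg, pg, k, rb_max, rp_max) {
  sb <- genome$seq[[bg$chrom]]
  sp <- genome$seq[[pg$chrom]]
  rb <- 0:rb_max
  rp <- 0:rp_max
  # frontier blocks (vectorised over r_b / r_p, combined with outer())
  bait_block_chr <- bait_char_from_end(sb, bg, rb, k + 1L)    # per r_b
  prey_block_chr <- prey_before_char(sp, pg, rp, k + 1L)      # per r_p
  bait_next <- bait_next_char(sb, bg, rb)                     # per r_b
  prey_at <- prey_at_char(sp, pg, rp)                         # per r_p
  ok <- outer(bait_block_chr, prey_block_chr, "!=") &
    outer(bait_next, prey_at, "!=")
  if (k >= 1L) {
    bait_sfx <- bait_suffix(sb, bg, rb, k)
    prey_bef <- prey_before(sp, pg, rp, k)
    ok <- ok & outer(bait_sfx, prey_bef, "==")
  }
  ok <- ok & outer(rb, rp, function(b, p) {
    junction_in_bounds(bg, pg, b, p, k, nchar(sb), nchar(sp))
  })
  idx <- which(ok, arr.ind = TRUE)
  data.frame(r_b = rb[idx[, 1]], r_p = rp[idx[, 2]])
}
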