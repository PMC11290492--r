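## Junction calling from bait-anchored reads.
##
## A read is anchored on the bait reference path (primer through the DSB and
## beyond) to locate the junction region, and the remainder is seeded against
## a genome-wide k-mer index. Each candidate prey diagonal is then fitted with
## a two-changepoint model over the whole read: positions before t1 are scored
## against the bait path, positions t1..t2-1 are unaligned gap (insertion)
## at GAP_COST per base, and positions from t2 on are scored against the prey
## diagonal. The (t1, t2) minimising total mismatch + gap cost give the bait
## end and the prey start (Qstart); ties prefer the smallest t2 (prey
## alignment maximal leftward, so junctional microhomology is attributed to
## the prey) and then the largest t1. B_Qend is the subsequent
## identity-maximal rightward extension of the bait alignment, which runs
## through any microhomology and stops at the first mismatch, so the query
## overlap B_Qend - Qstart + 1 recovers the MH length.
##
## Because the fit weighs both references at every position, an isolated
## sequencing error near the junction costs one mismatch under the true
## changepoint but several under any shifted one, so calls are robust to
## noise without lookahead heuristics; and on error-free reads the
## simulator's single-base frontier blocks make the true changepoint the
## strict optimum, so recovery is exact by construction rather than with
## high probability.

GAP_COST <- 0.45

#' Build a k-mer index of a toy genome
#'
#' Forward-strand k-mers of every chromosome keyed for binary search; minus
#' strand hits are found by looking up the reverse complement of a read k-mer.
#'
#' @param genome a `toy_genome`.
#' @param k k-mer size (default 20).
#' @return a `genome_index` (keyed data.table with `kmer`, `chrom`, `pos0`).
#' @export
genome_index <- function(genome, k = 20L) {
  tabs <- lapply(names(genome$seq), function(chrom) {
    s <- genome$seq[[chrom]]
    n <- nchar(s) - k + 1L
    data.table::data.table(
      kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
      chrom = chrom,
      pos0 = seq_len(n) - 1L
    )
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkeyv(idx, "kmer")
  structure(list(table = idx, k = k), class = "genome_index")
}

## Directional confirmed extension over a mismatch indicator vector.
## Walks window indices from `from` toward `to` in steps of `step`, returning
## the index of the last *matching* base reached and the remaining mismatch
## budget. `last = from - step` means no base was added.
confirmed_extend <- function(is_mm, from, to, step, budget) {
  last <- from - step
  if ((step > 0 && from > to) || (step < 0 && from < to)) {
    return(list(last = last, budget = budget))
  }
  i <- from
  lo <- min(from, to); hi <- max(from, to)
  while (i >= lo && i <= hi) {
    if (!is_mm[i]) {
      last <- i
      i <- i + step
      next
    }
    w4 <- i + step * (1:4)
    w13 <- i + step * (1:13)
    w4 <- w4[w4 >= lo & w4 <= hi]
    w13 <- w13[w13 >= lo & w13 <= hi]
    if (budget > 0 && length(w4) == 4L && !any(is_mm[w4]) &&
        sum(is_mm[w13]) <= 1L) {
      budget <- budget - 1L
      i <- i + step
    } else {
      break
    }
  }
  list(last = last, budget = budget)
}

#' Call junctions from a simulated library
#'
#' Anchors each read on its bait, finds candidate prey diagonals by k-mer
#' seeding against the genome index, fits the bait/gap/prey changepoint model
#' on each (see the header of this file), and emits tlx junction records for
#' the minimum-cost fit. Reads whose bait anchor fails, or whose post-bait
#' portion has no prey alignment (including unjoined bait-only reads), are
#' dropped; per-stage counts are reported alongside the calls.
#'
#' @param reads data.frame with `qname` and `seq` (e.g. `sim_library$reads`).
#' @param genome a `toy_genome`.
#' @param spec the `locus_spec`.
#' @param bait bait name in `spec`.
#' @param index optional prebuilt [genome_index()].
#' @param max_mismatch absorbed-mismatch budget of the preliminary bait-anchor
#'   scan used to place seeds (default 2).
#' @param min_prey minimum prey alignment length in bp (default 15).
#' @return list with `tlx` (junction records) and `stats` (data.frame of
#'   per-stage read counts).
#' @export
call_junctions <- function(reads, genome, spec, bait, index = NULL,
                           max_mismatch = 2L, min_prey = 15L) {
  if (inherits(reads, "sim_library")) reads <- reads$reads
  bg <- bait_geometry(bait_by_name(spec, bait))
  sb <- genome$seq[[bg$chrom]]
  if (is.null(index)) index <- genome_index(genome)
  k <- index$k
  n_reads <- nrow(reads)
  read_len <- nchar(reads$seq)

  ## ---- bait anchoring ----
  bait_ref <- seq_fwd(sb, bg$primer_outer, max(read_len), bg$dir)
  b_qend <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    mm <- logical(read_len[i])
    mm[mismatch_positions(reads$seq[i], bait_ref)] <- TRUE
    b_qend[i] <- confirmed_extend(mm, 1L, read_len[i], 1L, max_mismatch)$last
  }
  anchored <- b_qend >= bg$primer_len + 5L

  ## ---- batched seed lookup ----
  seed_list <- lapply(which(anchored), function(i) {
    q <- seq.int(max(b_qend[i] - (k - 1L), 1L), read_len[i] - k + 1L, by = 5L)
    data.table::data.table(read = i, q = q,
                           kmer = substring(reads$seq[i], q, q + k - 1L))
  })
  hits_by_read <- list()
  if (length(seed_list) > 0) {
    seeds <- data.table::rbindlist(seed_list)
    seeds[, rc := revcomp(kmer)]
    fwd <- index$table[seeds, on = "kmer", nomatch = NULL]
    fwd[, `:=`(dir = 1L, diag = pos0 - (q - 1L))]
    rev <- index$table[seeds, on = c(kmer = "rc"), nomatch = NULL]
    rev[, `:=`(dir = -1L, diag = (pos0 + k - 1L) + (q - 1L))]
    hits <- rbind(fwd[, c("read", "q", "chrom", "dir", "diag")],
                  rev[, c("read", "q", "chrom", "dir", "diag")])
    # one candidate per (chromosome, direction, diagonal); keep the earliest
    # seed so extension starts as close to the junction as possible
    data.table::setorderv(hits, c("read", "chrom", "dir", "diag", "q"))
    hits <- unique(hits, by = c("read", "chrom", "dir", "diag"))
    # the bait's own diagonal is not a prey
    hits <- hits[!(chrom == bg$chrom & dir == bg$dir & diag == bg$primer_outer)]
    hits_by_read <- split(hits, by = "read")
  }

  ## ---- per-read changepoint fit and record assembly ----
  t1_min <- bg$primer_len + 6L
  rows <- vector("list", n_reads)
  n_no_prey <- 0L
  for (i in which(anchored)) {
    cand <- hits_by_read[[as.character(i)]]
    best <- NULL
    n_i <- read_len[i]
    if (!is.null(cand)) {
      # bait-path mismatch indicator over the whole read
      mmb <- logical(n_i)
      mmb[mismatch_positions(reads$seq[i], bait_ref)] <- TRUE
      SB <- c(0L, cumsum(mmb))  # SB[t+1] = mismatches in read[1..t]
      for (ci in seq_len(nrow(cand))) {
        chrom <- cand$chrom[ci]; dir <- cand$dir[ci]; diag <- cand$diag[ci]
        q <- cand$q[ci]
        s <- genome$seq[[chrom]]
        L <- nchar(s)
        if (dir > 0) {
          j_lo <- max(1L, 1L - diag); j_hi <- min(n_i, L - diag)
          ref0_lo <- diag + (j_lo - 1L)
        } else {
          j_lo <- max(1L, diag - L + 2L); j_hi <- min(n_i, diag + 1L)
          ref0_lo <- diag - (j_lo - 1L)
        }
        win <- j_hi - j_lo + 1L
        if (win < k) next
        ref_str <- seq_fwd(s, ref0_lo, win, dir)
        qry_str <- substr(reads$seq[i], j_lo, j_hi)
        mmp <- logical(win)
        mmp[mismatch_positions(qry_str, ref_str)] <- TRUE
        qend <- j_hi
        # t2 candidates: from the window start up to the seed (which matches
        # the prey exactly)
        t2s <- seq.int(max(j_lo, t1_min), q)
        if (length(t2s) == 0) next
        # SP[t2] = prey mismatches in read[t2..qend]
        sp_all <- rev(cumsum(rev(mmp)))
        SP <- sp_all[t2s - j_lo + 1L]
        # best bait part for each t2: min over t1 in [t1_min, t2] of
        # SB[t1-1] - GAP_COST * t1, largest t1 on ties
        t1s <- seq.int(t1_min, max(t2s))
        A <- SB[t1s] - GAP_COST * t1s
        # running minimum of A, keeping the largest t1 on ties
        cmA <- numeric(length(A))
        best_t1 <- integer(length(A))
        cur <- Inf; cur_t1 <- t1s[1]
        for (z in seq_along(A)) {
          if (A[z] <= cur) { cur <- A[z]; cur_t1 <- t1s[z] }
          cmA[z] <- cur
          best_t1[z] <- cur_t1
        }
        costs <- cmA[t2s - t1_min + 1L] + GAP_COST * t2s + SP
        zbest <- which.min(costs)  # smallest t2 on ties
        t2 <- t2s[zbest]
        t1 <- best_t1[t2 - t1_min + 1L]
        cost <- costs[zbest]
        alen <- qend - t2 + 1L
        if (alen < min_prey) next
        if (dir > 0) {
          r_lo <- diag + (t2 - 1L); r_hi <- diag + (qend - 1L)
          junction0 <- r_lo
        } else {
          r_hi <- diag - (t2 - 1L); r_lo <- diag - (qend - 1L)
          junction0 <- r_hi
        }
        fit <- list(cost = cost, t1 = t1, qstart = t2, qend = qend,
                    alen = alen, chrom = chrom, dir = dir,
                    r_lo = r_lo, r_hi = r_hi, junction0 = junction0)
        if (is.null(best) ||
            cost < best$cost ||
            (cost == best$cost && (t2 < best$qstart ||
              (t2 == best$qstart && (r_lo < best$r_lo ||
                (r_lo == best$r_lo && dir > best$dir)))))) {
          best <- fit
        }
      }
    }
    if (is.null(best)) {
      n_no_prey <- n_no_prey + 1L
      next
    }
    # identity-maximal rightward bait extension: runs through junctional
    # microhomology and stops at the first bait-path mismatch
    bq <- best$t1 - 1L
    while (bq + 1L <= n_i && !mmb[bq + 1L]) bq <- bq + 1L
    b_jb0 <- bg$primer_outer + bg$dir * (bq - 1L)
    rows[[i]] <- data.frame(
      Qname = reads$qname[i],
      JuncID = 0L,
      Rname = best$chrom,
      Junction = best$junction0 + 1L,
      Strand = if (best$dir > 0) "+" else "-",
      Rstart = best$r_lo + 1L,
      Rend = best$r_hi + 1L,
      B_Rname = bg$chrom,
      B_Rstart = min(bg$primer_outer, b_jb0) + 1L,
      B_Rend = max(bg$primer_outer, b_jb0) + 1L,
      B_Strand = if (bg$dir > 0) "+" else "-",
      B_Junction = b_jb0 + 1L,
      B_Qstart = 1L,
      B_Qend = bq,
      Qstart = best$qstart,
      Qend = best$qend,
      Qlen = n_i,
      Seq = reads$seq[i],
      stringsAsFactors = FALSE
    )
  }
  called <- data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)])
  tlx <- as.data.frame(called)
  if (nrow(tlx) > 0) tlx$JuncID <- seq_len(nrow(tlx))
  stats <- data.frame(
    stage = c("input", "bait_anchored", "no_prey_alignment", "junctions"),
    reads = c(n_reads, sum(anchored), n_no_prey, nrow(tlx)),
    stringsAsFactors = FALSE
  )
  list(tlx = tlx, stats = stats)
}
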