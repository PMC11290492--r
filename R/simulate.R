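#' Simulate a bait-anchored repair library
#'
#' Generates one junction-bearing read per read pair from a single bait,
#' together with a ground-truth table recording, for every read, the event
#' class (V-J joint, bait rejoin, translocation, or unjoined), the partner,
#' the per-end resections, and the intended joint structure. Microhomology is
#' realised physically: an MH-k junction is only placed at bait/prey resection
#' pairs where the k terminal bait bases are identical to the k reference
#' bases immediately upstream of the prey junction, with single-base blocking
#' mismatches on both frontiers, so the emergent sequence structure of every
#' noiseless read equals its intended structure. Substitution noise is applied
#' after the truth coordinates are recorded.
#'
#' @param config a [sim_config()].
#' @param spec a `locus_spec`.
#' @param genome a `toy_genome` built from the same spec.
#' @return a `sim_library`: list with `reads` (data.frame `qname`, `seq`),
#'   `truth` (one row per read), `config`, and `bait`.
#' @export
simulate_library <- function(config, spec, genome) {
  validate_sim_config(config)
  with_seed(config$seed, {
    out <- sim_core(config, spec, genome, config$n_read_pairs)
    # exact-duplicate injection (dedup testing only)
    if (config$duplicate_rate > 0) {
      dup <- which(stats::runif(nrow(out$reads)) < config$duplicate_rate)
      if (length(dup) > 0) {
        reads2 <- out$reads[dup, ]
        truth2 <- out$truth[dup, ]
        reads2$qname <- paste0(reads2$qname, ":dup")
        truth2$qname <- reads2$qname
        truth2$is_duplicate <- TRUE
        out$reads <- rbind(out$reads, reads2)
        out$truth <- rbind(out$truth, truth2)
      }
    }
    structure(list(reads = out$reads, truth = out$truth, config = config,
                   bait = config$bait), class = "sim_library")
  })
}

#' Simulate a single repair event
#'
#' Draws one event from the configured event, segment, end-type, resection and
#' structure distributions and returns its ground-truth record. Uses the
#' session RNG state (seed the caller's stream for reproducibility);
#' [simulate_library()] is the seeded batch interface.
#'
#' @inheritParams simulate_library
#' @return one-row ground-truth data.frame.
#' @export
simulate_event <- function(config, spec, genome) {
  sim_core(config, spec, genome, 1L)$truth
}

## ------------------------------------------------------------------------
## internals

sim_core <- function(cfg, spec, genome, n) {
  bait <- bait_by_name(spec, cfg$bait)
  bg <- bait_geometry(bait)
  sb <- genome$seq[[bg$chrom]]
  rb_max <- min(cfg$resection_max, bg$rb_headroom)
  rp_max <- cfg$resection_max
  if (cfg$read_length < bait_len(bg, 0L) + 45L) {
    stop("read_length too short to reach the junction from the bait primer",
         call. = FALSE)
  }
  pmf_b <- resection_pmf(cfg$resection_w0, cfg$resection_mean, rb_max)
  pmf_p <- resection_pmf(cfg$resection_w0, cfg$resection_mean, rp_max)

  vseg <- spec$segments[spec$segments$role == "V", ]
  v_stad <- stad_of(vseg$cut_site, spec)
  if (!all(names(cfg$v_usage) %in% spec$stads$label)) {
    stop("v_usage names must be sTAD labels", call. = FALSE)
  }

  classes <- sample(c("V_J", "rejoin", "translocation", "unjoined"), n,
                    replace = TRUE,
                    prob = c(cfg$vj_rate, cfg$rejoin_rate,
                             cfg$translocation_rate,
                             1 - cfg$vj_rate - cfg$rejoin_rate -
                               cfg$translocation_rate))

  tr <- data.frame(
    qname = sprintf("rd%07d", seq_len(n)),
    event_class = classes,
    prey_segment = NA_character_,
    prey_end_type = NA_character_,
    configuration = NA_character_,
    bait_resection = NA_integer_,
    prey_resection = NA_integer_,
    structure_kind = NA_character_,
    structure_length = NA_integer_,
    palindromic = NA,
    translocation_class = NA_character_,
    prey_chrom = NA_character_,
    prey_dir = NA_integer_,
    prey_jb = NA_integer_,
    mh_len = NA_integer_,
    ins_len = NA_integer_,
    ins_seq = NA_character_,
    stad = NA_character_,
    prey_offset = NA_integer_,
    is_duplicate = FALSE,
    stringsAsFactors = FALSE
  )

  site_cache <- new.env(parent = emptyenv())
  get_sites <- function(pg, key, k) {
    id <- paste0(key, "|", k)
    if (is.null(site_cache[[id]])) {
      s <- junction_sites(genome, bg, pg, k, rb_max, rp_max)
      s$w <- pmf_b[s$r_b + 1L] * pmf_p[s$r_p + 1L]
      site_cache[[id]] <- s
    }
    site_cache[[id]]
  }

  w <- cfg$structure_weights
  bins <- names(w)[w > 0]
  parse_bin <- function(b) {
    if (b == "direct") c("direct", 0L)
    else if (startsWith(b, "MH")) c("MH", as.integer(sub("MH", "", b)))
    else c("insertion", as.integer(sub("INS", "", b)))
  }

  ## --- V-J events --------------------------------------------------------
  iv <- which(classes == "V_J")
  if (length(iv) > 0) {
    stad_draw <- sample(names(cfg$v_usage), length(iv), replace = TRUE,
                        prob = cfg$v_usage)
    seg_name <- vapply(stad_draw, function(st) {
      cand <- vseg$name[v_stad == st]
      if (length(cand) == 0) stop("no V segment in sTAD ", st, call. = FALSE)
      if (length(cand) == 1) cand else sample(cand, 1L)
    }, "")
    cognate <- bait$side
    noncog <- if (cognate == "CE") "SE" else "CE"
    end <- ifelse(stats::runif(length(iv)) < cfg$hybrid_rate, noncog, cognate)
    bin <- sample(bins, length(iv), replace = TRUE, prob = w[bins])

    tr$prey_segment[iv] <- seg_name
    tr$prey_end_type[iv] <- end
    seg_idx <- match(seg_name, vseg$name)
    tr$configuration[iv] <- vseg$configuration[seg_idx]
    tr$stad[iv] <- v_stad[seg_idx]

    for (j in seq_along(iv)) {
      i <- iv[j]
      seg <- vseg[seg_idx[j], ]
      pg <- prey_geometry_v(seg, end[j])
      key <- paste0(seg$name, ":", end[j])
      res <- engineer_junction(genome, bg, pg, key, bin[j], cfg, pmf_b, pmf_p,
                               rb_max, rp_max, get_sites, parse_bin, bins, w,
                               pal_allowed = (bait$side == "CE"))
      tr <- store_event(tr, i, pg, res)
      tr$prey_offset[i] <- cut_site_offset(res$f0, seg)
    }
  }

  ## --- rejoins ------------------------------------------------------------
  ir <- which(classes == "rejoin")
  if (length(ir) > 0) {
    pg <- prey_geometry_rejoin(bg)
    bin <- sample(bins, length(ir), replace = TRUE, prob = w[bins])
    for (j in seq_along(ir)) {
      i <- ir[j]
      res <- engineer_junction(genome, bg, pg, "rejoin", bin[j], cfg, pmf_b,
                               pmf_p, rb_max, rp_max, get_sites, parse_bin,
                               bins, w, pal_allowed = (bait$side == "CE"))
      if (is.null(res)) {
        # perfect religation: no junction exists; the read is the unbroken
        # reference continuation (resection columns stay NA)
        tr$structure_kind[i] <- "none"
        tr$prey_segment[i] <- "bait"
        next
      }
      tr <- store_event(tr, i, pg, res)
      tr$prey_segment[i] <- "bait"
    }
  }

  ## --- translocations -----------------------------------------------------
  it <- which(classes == "translocation")
  if (length(it) > 0) {
    tclass <- sample(names(cfg$translocation_split), length(it), replace = TRUE,
                     prob = cfg$translocation_split)
    bin <- sample(bins, length(it), replace = TRUE, prob = w[bins])
    for (j in seq_along(it)) {
      i <- it[j]
      res <- engineer_translocation(genome, spec, bg, tclass[j], bin[j], cfg,
                                    pmf_b, pmf_p, rb_max, rp_max, parse_bin,
                                    pal_allowed = (bait$side == "CE"))
      tr <- store_event(tr, i, res$pg, res)
      tr$translocation_class[i] <- tclass[j]
      tr$prey_segment[i] <- res$partner_label
      tr$prey_resection[i] <- NA_integer_  # no cut site to measure from
    }
  }

  ## --- read assembly ------------------------------------------------------
  reads <- assemble_reads(tr, bg, genome, cfg)
  reads <- apply_substitution_noise(reads, cfg$error_rate)
  list(reads = data.frame(qname = tr$qname, seq = reads,
                          stringsAsFactors = FALSE),
       truth = tr)
}

store_event <- function(tr, i, pg, res) {
  tr$bait_resection[i] <- res$r_b
  tr$prey_resection[i] <- res$r_p
  tr$structure_kind[i] <- res$kind
  tr$structure_length[i] <- res$len
  tr$palindromic[i] <- res$palindromic
  tr$prey_chrom[i] <- pg$chrom
  tr$prey_dir[i] <- pg$dir
  tr$prey_jb[i] <- prey_jb(pg, res$r_p)
  tr$mh_len[i] <- if (res$kind == "MH") res$len else 0L
  tr$ins_len[i] <- if (res$kind == "insertion") res$len else 0L
  tr$ins_seq[i] <- res$ins
  tr
}

## Engineer one junction of the requested structure on a fixed flank pair.
## Falls back to a structure bin that is realisable on this flank pair when
## the requested microhomology has no admissible (r_b, r_p) site; the truth
## table always records the realised structure.
engineer_junction <- function(genome, bg, pg, key, bin, cfg, pmf_b, pmf_p,
                              rb_max, rp_max, get_sites, parse_bin, bins, w,
                              pal_allowed) {
  pb <- parse_bin(bin)
  kind <- pb[1]; len <- as.integer(pb[2])
  if (kind == "insertion") {
    return(engineer_insertion(genome, bg, pg, len, cfg, pmf_b, pmf_p,
                              rb_max, rp_max, pal_allowed))
  }
  k <- if (kind == "MH") len else 0L
  # a site is realisable only where the resection mixture puts mass on it
  live <- function(s) s[s$w > 0, , drop = FALSE]
  sites <- live(get_sites(pg, key, k))
  if (nrow(sites) == 0) {
    # no admissible positive-weight site for this MH length on this flank
    # pair: redraw the structure among bins realisable here
    for (alt in sample(bins, length(bins), prob = w[bins], replace = FALSE)) {
      pa <- parse_bin(alt)
      if (pa[1] == "insertion") {
        return(engineer_insertion(genome, bg, pg, as.integer(pa[2]), cfg,
                                  pmf_b, pmf_p, rb_max, rp_max, pal_allowed))
      }
      k2 <- if (pa[1] == "MH") as.integer(pa[2]) else 0L
      sites <- live(get_sites(pg, key, k2))
      if (nrow(sites) > 0) { kind <- pa[1]; len <- as.integer(pa[2]); k <- k2; break }
    }
    if (nrow(sites) == 0) {
      if (key == "rejoin") {
        # the only mass sits on seamless religation (e.g. resection_w0 = 1):
        # the molecule reconstitutes the unbroken reference and carries no
        # junction -- report a perfect, undetectable rejoin
        return(NULL)
      }
      stop("no realisable junction on flank ", key,
           " under the configured resection mixture", call. = FALSE)
    }
  }
  row <- sites[sample.int(nrow(sites), 1L, prob = sites$w), ]
  list(kind = kind, len = len, r_b = row$r_b, r_p = row$r_p,
       ins = "", palindromic = FALSE,
       f0 = prey_jb(pg, row$r_p) - pg$dir * k, pg = pg)
}

## An insertion junction is admissible when no shifted changepoint fit can
## beat the true one on the noiseless read: the cumulative mismatch count of
## any y trailing read bases (junk, then bait) against the prey reference
## upstream of the junction must exceed GAP_COST * y (otherwise re-aligning
## those bases to the prey and shrinking the gap would be cheaper), and
## symmetrically for leading junk against the bait-path continuation. The
## y = 1 / x = 1 cases are the usual single-base frontier blocks.
insertion_admissible <- function(genome, bg, pg, r_b, r_p, ins, g = 0.45) {
  sb <- genome$seq[[bg$chrom]]
  sp <- genome$seq[[pg$chrom]]
  m <- nchar(ins)
  # leading junk vs bait continuation
  cont <- seq_fwd(sb, bait_jb(bg, r_b) + bg$dir, m, bg$dir)
  if (nchar(cont) < m) return(FALSE)
  mm_lead <- cumsum(strsplit(ins, "")[[1]] != strsplit(cont, "")[[1]])
  if (any(mm_lead <= g * seq_len(m))) return(FALSE)
  # trailing (junk, then bait) walk vs prey upstream
  l_b <- bait_len(bg, r_b)
  y_max <- l_b + m - 26L  # deeper shifts would consume the primer anchor
  y_max <- min(y_max, l_b - 1L + m)
  u <- prey_before(sp, pg, r_p, y_max)
  if (nchar(u) < y_max) return(FALSE)
  left_ctx <- paste0(bait_suffix(sb, bg, r_b, y_max - m), ins)
  mm <- rev(strsplit(left_ctx, "")[[1]]) != rev(strsplit(u, "")[[1]])
  if (any(cumsum(mm) <= g * seq_len(y_max))) return(FALSE)
  TRUE
}

engineer_insertion <- function(genome, bg, pg, m, cfg, pmf_b, pmf_p,
                               rb_max, rp_max, pal_allowed) {
  sb <- genome$seq[[bg$chrom]]
  sp <- genome$seq[[pg$chrom]]
  want_pal <- pal_allowed && m <= 4L &&
    stats::runif(1) < cfg$palindromic_insertion_rate
  for (attempt in seq_len(60L)) {
    r_b <- sample(0:rb_max, 1L, prob = pmf_b)
    r_p <- sample(0:rp_max, 1L, prob = pmf_p)
    if (want_pal) {
      # P-nucleotide-like: reverse complement of the bait-proximal flank
      ins <- revcomp(bait_suffix(sb, bg, r_b, m))
      if (insertion_admissible(genome, bg, pg, r_b, r_p, ins)) {
        return(list(kind = "insertion", len = m, r_b = r_b, r_p = r_p,
                    ins = ins, palindromic = TRUE,
                    f0 = prey_jb(pg, r_p), pg = pg))
      }
      next
    }
    ins <- paste(sample(DNA_BASES, m, replace = TRUE), collapse = "")
    # avoid accidental palindromes so the emergent flag equals the intent
    bait_prox <- bait_suffix(sb, bg, r_b, m)
    prey_prox <- seq_fwd(sp, prey_jb(pg, r_p), m, pg$dir)
    if (ins == revcomp(bait_prox) || ins == revcomp(prey_prox)) next
    if (insertion_admissible(genome, bg, pg, r_b, r_p, ins)) {
      return(list(kind = "insertion", len = m, r_b = r_b, r_p = r_p,
                  ins = ins, palindromic = FALSE,
                  f0 = prey_jb(pg, r_p), pg = pg))
    }
  }
  if (want_pal) {
    # palindromic construction kept colliding with the admissibility
    # constraints: emit a non-palindromic insertion instead (truth records
    # what was realised)
    return(engineer_insertion(genome, bg, pg, m, utils::modifyList(
      cfg, list(palindromic_insertion_rate = 0)), pmf_b, pmf_p,
      rb_max, rp_max, FALSE))
  }
  stop("could not construct an admissible insertion junction", call. = FALSE)
}

engineer_translocation <- function(genome, spec, bg, tclass, bin, cfg,
                                   pmf_b, pmf_p, rb_max, rp_max, parse_bin,
                                   pal_allowed) {
  margin <- 300L
  sample_point <- function() {
    if (tclass == "receptor_locus") {
      r <- spec$receptor_loci[sample.int(nrow(spec$receptor_loci), 1L), ]
      list(chrom = r$chrom,
           pos = sample(seq.int(r$start, r$end - 1L), 1L),
           label = r$label)
    } else {
      # spontaneous partners live on non-bait chromosomes, outside the
      # annotated receptor loci
      lens <- spec$chrom_lengths[names(spec$chrom_lengths) != spec$locus$chrom]
      repeat {
        chrom <- sample(names(lens), 1L, prob = lens - 2 * margin)
        pos <- sample(seq.int(margin, lens[[chrom]] - margin), 1L)
        rl <- spec$receptor_loci
        inside <- any(rl$chrom == chrom & rl$start <= pos & pos < rl$end)
        if (!inside) break
      }
      list(chrom = chrom, pos = pos, label = paste0("spont:", chrom, ":", pos))
    }
  }
  w <- cfg$structure_weights
  bins <- names(w)[w > 0]
  try_bin <- function(b, pg, pt) {
    pb <- parse_bin(b)
    kind <- pb[1]; len <- as.integer(pb[2])
    if (kind == "insertion") {
      res <- tryCatch(
        engineer_insertion(genome, bg, pg, len, cfg, pmf_b, pmf_p,
                           rb_max, rp_max, pal_allowed),
        error = function(e) NULL)
      if (!is.null(res)) res$partner_label <- pt$label
      return(res)
    }
    k <- if (kind == "MH") len else 0L
    sites <- junction_sites(genome, bg, pg, k, rb_max, rp_max)
    sites$w <- pmf_b[sites$r_b + 1L] * pmf_p[sites$r_p + 1L]
    sites <- sites[sites$w > 0, , drop = FALSE]
    if (nrow(sites) == 0) return(NULL)
    row <- sites[sample.int(nrow(sites), 1L, prob = sites$w), ]
    list(kind = kind, len = len, r_b = row$r_b, r_p = row$r_p,
         ins = "", palindromic = FALSE,
         f0 = prey_jb(pg, row$r_p) - pg$dir * k, pg = pg,
         partner_label = pt$label)
  }
  for (attempt in seq_len(25L)) {
    pt <- sample_point()
    dir <- sample(c(-1L, 1L), 1L)
    pg <- prey_geometry_point(pt$chrom, pt$pos, dir)
    res <- try_bin(bin, pg, pt)
    if (!is.null(res)) return(res)
    if (attempt > 5L) {
      # the requested structure keeps failing at the sampled partner points
      # (e.g. a long microhomology under a degenerate resection mixture):
      # fall back to a structure realisable here, as on the V flanks
      for (alt in sample(bins, length(bins), prob = w[bins])) {
        res <- try_bin(alt, pg, pt)
        if (!is.null(res)) return(res)
      }
    }
  }
  stop("could not place translocation junction after 25 attempts",
       call. = FALSE)
}

assemble_reads <- function(tr, bg, genome, cfg) {
  sb <- genome$seq[[bg$chrom]]
  n <- nrow(tr)
  reads <- character(n)

  # unjoined reads and perfect (seamless) rejoins both read the unbroken
  # allele: bait flank straight through the cut site
  unj <- tr$event_class == "unjoined" | is.na(tr$bait_resection)
  if (any(unj)) {
    reads[unj] <- seq_fwd(sb, bg$primer_outer, cfg$read_length, bg$dir)
  }

  joined <- which(!unj)
  if (length(joined) > 0) {
    L_b <- bait_len(bg, tr$bait_resection[joined])
    jb <- bait_jb(bg, tr$bait_resection[joined])
    bait_part <- if (bg$dir > 0) {
      substring(sb, bg$primer_outer + 1L, jb + 1L)
    } else {
      revcomp(substring(sb, jb + 1L, bg$primer_outer + 1L))
    }
    ins <- ifelse(is.na(tr$ins_seq[joined]), "", tr$ins_seq[joined])
    prey_len <- cfg$read_length - L_b - nchar(ins)
    prey_part <- character(length(joined))
    grp <- paste0(tr$prey_chrom[joined], "/", tr$prey_dir[joined])
    for (g in unique(grp)) {
      sel <- grp == g
      chrom <- tr$prey_chrom[joined][sel][1]
      dir <- tr$prey_dir[joined][sel][1]
      sp <- genome$seq[[chrom]]
      f0 <- tr$prey_jb[joined][sel]
      pl <- prey_len[sel]
      prey_part[sel] <- if (dir > 0) {
        substring(sp, f0 + 1L, f0 + pl)
      } else {
        revcomp(substring(sp, f0 - pl + 2L, f0 + 1L))
      }
    }
    if (any(nchar(prey_part) != prey_len)) {
      stop("prey flank runs off its chromosome; enlarge the toy genome",
           call. = FALSE)
    }
    reads[joined] <- paste0(bait_part, ins, prey_part)
  }
  reads
}

apply_substitution_noise <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  len <- nchar(reads)
  n_err <- stats::rbinom(length(reads), len, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  reads
}

#' Convert ground truth to tlx junction records
#'
#' Emits, for every joined read, the tlx record a query-maximal caller would
#' produce on the noiseless read: the bait alignment runs from the primer to
#' the junction, microhomology bases are attributed to the prey (maximal
#' leftward prey extension), and insertions separate the two alignments. This
#' bypass lets the classifier and metrics layers be tested without the
#' read-level caller.
#'
#' @param sim a `sim_library`.
#' @param spec the `locus_spec` used to simulate.
#' @return a tlx data.frame (see [read_tlx()] for the dialect).
#' @export
emit_truth_tlx <- function(sim, spec) {
  tr <- sim$truth
  bait <- bait_by_name(spec, sim$bait)
  bg <- bait_geometry(bait)
  cfg <- sim$config
  # perfect (seamless) rejoins carry no junction and emit no record
  joined <- which(tr$event_class != "unjoined" & !is.na(tr$bait_resection))
  tr <- tr[joined, ]
  reads <- sim$reads$seq[joined]

  L_b <- bait_len(bg, tr$bait_resection)
  jb <- bait_jb(bg, tr$bait_resection)
  b_lo <- pmin(bg$primer_outer, jb); b_hi <- pmax(bg$primer_outer, jb)
  mh <- tr$mh_len; insl <- tr$ins_len
  f0 <- tr$prey_jb - tr$prey_dir * mh
  prey_span <- cfg$read_length - L_b - insl + mh
  l0 <- tr$prey_jb + tr$prey_dir * (cfg$read_length - L_b - insl - 1L)
  p_lo <- pmin(f0, l0); p_hi <- pmax(f0, l0)

  data.frame(
    Qname = tr$qname,
    JuncID = seq_len(nrow(tr)),
    Rname = tr$prey_chrom,
    Junction = f0 + 1L,
    Strand = ifelse(tr$prey_dir > 0, "+", "-"),
    Rstart = p_lo + 1L,
    Rend = p_hi + 1L,
    B_Rname = bg$chrom,
    B_Rstart = b_lo + 1L,
    B_Rend = b_hi + 1L,
    B_Strand = if (bg$dir > 0) "+" else "-",
    B_Junction = jb + 1L,
    B_Qstart = 1L,
    B_Qend = L_b,
    Qstart = L_b - mh + insl + 1L,
    Qend = cfg$read_length,
    Qlen = cfg$read_length,
    Seq = reads,
    stringsAsFactors = FALSE
  )
}

#' Write a simulated library to disk
#'
#' Writes the reads as FASTQ (constant Q30 placeholder qualities) and the
#' ground-truth table as a tab-delimited file; both are byte-deterministic
#' for a given configuration and seed.
#'
#' @param sim a `sim_library`.
#' @param fastq_file,truth_file output paths.
#' @return invisibly, the two paths.
#' @export
write_library <- function(sim, fastq_file, truth_file) {
  ss <- Biostrings::DNAStringSet(sim$reads$seq)
  names(ss) <- sim$reads$qname
  qual <- Biostrings::BStringSet(strrep("?", nchar(sim$reads$seq)))
  Biostrings::writeXStringSet(ss, fastq_file, format = "fastq",
                              qualities = qual)
  utils::write.table(sim$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq_file, truth_file))
}

#' @export
print.sim_library <- function(x, ...) {
  cat("<sim_library> ", nrow(x$reads), " reads from bait ", x$bait, "\n",
      sep = "")
  print(table(x$truth$event_class))
  invisible(x)
}
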