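## Junction classification: joint structure from query coordinates, event
## category from the junction's genomic position, prey end type and
## configuration for V-region junctions, and the strand-normalised resection
## offset from the assigned cut site.

#' Joint structure from bait/prey query coordinates
#'
#' The bait-prey query overlap `o = B_Qend - Qstart + 1` defines the joint
#' structure: `o >= 1` is microhomology of length `o`, `o == 0` a direct
#' joint, and `o < 0` an insertion of length `-o`. Insertions are additionally
#' tested for palindromy: an insertion is flagged palindromic when it equals
#' the reverse complement of the adjacent bait-proximal or prey-proximal read
#' bases. Structures longer than `max_len` are flagged out of range.
#'
#' @param tlx data.frame of junction records.
#' @param max_len largest structure length binned (default 20).
#' @return data.frame with `structure_kind` (`"MH"`, `"direct"`,
#'   `"insertion"`), `structure_length`, `palindromic`, `out_of_range`.
#' @export
joint_structure <- function(tlx, max_len = 20L) {
  o <- tlx$B_Qend - tlx$Qstart + 1L
  kind <- ifelse(o >= 1L, "MH", ifelse(o == 0L, "direct", "insertion"))
  len <- abs(o)
  pal <- rep(FALSE, nrow(tlx))
  ins_idx <- which(kind == "insertion")
  for (i in ins_idx) {
    m <- len[i]
    ins <- substr(tlx$Seq[i], tlx$B_Qend[i] + 1L, tlx$B_Qend[i] + m)
    bait_flank <- substr(tlx$Seq[i], tlx$B_Qend[i] - m + 1L, tlx$B_Qend[i])
    prey_flank <- substr(tlx$Seq[i], tlx$Qstart[i], tlx$Qstart[i] + m - 1L)
    pal[i] <- (nchar(bait_flank) == m && ins == revcomp(bait_flank)) ||
      (nchar(prey_flank) == m && ins == revcomp(prey_flank))
  }
  data.frame(structure_kind = kind,
             structure_length = as.integer(len),
             palindromic = pal,
             out_of_range = len > max_len,
             stringsAsFactors = FALSE)
}

#' Categorise junctions by genomic position
#'
#' Assigns each junction to one of: `rejoin` (junction inside the bait
#' region), `V_J` (within `pad` bp of a V-segment cut site, inclusive on both
#' sides), `intra_locus_other` (elsewhere inside the locus interval on the
#' bait chromosome), or `translocation` (anything else), with translocations
#' split into `receptor_locus` and `spontaneous` partners.
#'
#' @param tlx data.frame of junction records.
#' @param spec a `locus_spec`.
#' @param bait bait name (defines the rejoin region).
#' @param pad V-region window half-width in bp (default 200).
#' @return data.frame with `category`, `prey_segment` (V name or `NA`),
#'   `translocation_class` (or `NA`).
#' @export
categorize <- function(tlx, spec, bait, pad = 200L) {
  b <- bait_by_name(spec, bait)
  n <- nrow(tlx)
  category <- rep("translocation", n)
  prey_segment <- rep(NA_character_, n)
  tclass <- rep(NA_character_, n)
  j0 <- tlx$Junction - 1L

  vseg <- spec$segments[spec$segments$role == "V", ]
  on_bait_chrom <- tlx$Rname == spec$locus$chrom
  # nearest V cut site within the window
  for (i in seq_len(n)) {
    if (!on_bait_chrom[i]) next
    if (j0[i] >= b$region_start && j0[i] < b$region_end) {
      category[i] <- "rejoin"
      next
    }
    d <- abs(j0[i] - vseg$cut_site)
    nearest <- which.min(d)
    if (d[nearest] <= pad) {
      category[i] <- "V_J"
      prey_segment[i] <- vseg$name[nearest]
    } else if (j0[i] >= spec$locus$start && j0[i] < spec$locus$end) {
      category[i] <- "intra_locus_other"
    }
  }
  is_tr <- category == "translocation"
  if (any(is_tr)) {
    rl <- spec$receptor_loci
    tclass[is_tr] <- "spontaneous"
    if (nrow(rl) > 0) {
      for (r in seq_len(nrow(rl))) {
        hit <- is_tr & tlx$Rname == rl$chrom[r] &
          j0 >= rl$start[r] & j0 < rl$end[r]
        tclass[hit] <- "receptor_locus"
      }
    }
  }
  data.frame(category = category, prey_segment = prey_segment,
             translocation_class = tclass, stringsAsFactors = FALSE)
}

#' Prey end type of V-region junctions
#'
#' Votes each aligned prey reference base to the coding or signal side of the
#' assigned V segment's cut site (coding side: strand-normalised offset <= 0)
#' and assigns the majority side; ties go to the side containing the junction
#' base itself. `end_ambiguous` is set when the alignment spans both sides.
#'
#' @param tlx data.frame of junction records.
#' @param cat output of [categorize()] (needs `prey_segment`).
#' @param spec a `locus_spec`.
#' @return data.frame with `prey_end_type` (`"CE"`/`"SE"`/`NA`),
#'   `end_ambiguous`, `configuration`.
#' @export
assign_end_type <- function(tlx, cat, spec) {
  n <- nrow(tlx)
  end <- rep(NA_character_, n)
  amb <- rep(NA, n)
  config <- rep(NA_character_, n)
  for (i in which(!is.na(cat$prey_segment))) {
    seg <- segment_by_name(spec, cat$prey_segment[i])
    offs <- cut_site_offset(seq.int(tlx$Rstart[i] - 1L, tlx$Rend[i] - 1L), seg)
    n_ce <- sum(offs <= 0L)
    n_se <- sum(offs > 0L)
    if (n_ce != n_se) {
      end[i] <- if (n_ce > n_se) "CE" else "SE"
    } else {
      end[i] <- if (cut_site_offset(tlx$Junction[i] - 1L, seg) <= 0L) "CE"
                else "SE"
    }
    amb[i] <- n_ce > 0L && n_se > 0L
    config[i] <- seg$configuration
  }
  data.frame(prey_end_type = end, end_ambiguous = amb,
             configuration = config, stringsAsFactors = FALSE)
}

#' Classify called junctions
#'
#' One-stop annotation: joint structure, positional category, prey end type
#' and configuration, the strand-normalised resection offset of the junction
#' from its assigned V cut site, and the sub-TAD of the assigned V segment.
#'
#' @param tlx data.frame of junction records.
#' @param spec a `locus_spec`.
#' @param bait bait name.
#' @param pad V-region window half-width (default 200).
#' @return the tlx records with classification columns appended.
#' @export
classify_junctions <- function(tlx, spec, bait, pad = 200L) {
  if (nrow(tlx) == 0) {
    out <- tlx
    for (col in c("structure_kind", "category", "prey_segment",
                  "translocation_class", "prey_end_type", "configuration",
                  "stad")) out[[col]] <- character(0)
    out$structure_length <- integer(0)
    out$palindromic <- logical(0)
    out$out_of_range <- logical(0)
    out$end_ambiguous <- logical(0)
    out$resection_offset <- integer(0)
    return(out)
  }
  st <- joint_structure(tlx)
  cat <- categorize(tlx, spec, bait, pad)
  et <- assign_end_type(tlx, cat, spec)
  offset <- rep(NA_integer_, nrow(tlx))
  stad <- rep(NA_character_, nrow(tlx))
  for (i in which(!is.na(cat$prey_segment))) {
    seg <- segment_by_name(spec, cat$prey_segment[i])
    offset[i] <- cut_site_offset(tlx$Junction[i] - 1L, seg)
    stad[i] <- stad_of(seg$cut_site, spec, seg$chrom)
  }
  cbind(tlx, st, cat, et,
        data.frame(resection_offset = offset, stad = stad,
                   stringsAsFactors = FALSE))
}
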