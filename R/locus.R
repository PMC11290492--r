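#' Locus coordinate model
#'
#' A `locus_spec` bundles everything the simulator, caller and classifier need
#' to know about the toy antigen-receptor locus: V/J segment annotations with
#' RAG1/2 cut sites, bait definitions (which side of the J DSB the library is
#' anchored on), the sub-TAD partition of the V region, and the off-target
#' RAG-active receptor loci on other chromosomes.
#'
#' Coordinates are 0-based, half-open `[start, end)` internally. `cut_site` is
#' the 0-based coordinate of the cut-adjacent *coding* base, so that the
#' strand-normalised offset of a zero-resection coding-end junction is exactly
#' 0 and signal-side positions have offset > 0 (see [cut_site_offset()]).
#'
#' @name locus_spec
NULL

new_locus_spec <- function(segments, baits, stads, locus, receptor_loci,
                           chrom_lengths) {
  spec <- structure(
    list(segments = segments, baits = baits, stads = stads, locus = locus,
         receptor_loci = receptor_loci, chrom_lengths = chrom_lengths),
    class = "locus_spec"
  )
  validate_locus_spec(spec)
}

#' Validate a locus specification
#'
#' Checks every structural invariant of the coordinate model and fails with a
#' message naming the offending record.
#'
#' @param spec a `locus_spec`.
#' @return the validated spec, invisibly usable.
#' @export
validate_locus_spec <- function(spec) {
  seg <- spec$segments
  stopifnot(is.data.frame(seg), nrow(seg) >= 1)
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (is.na(s$cut_site)) {
      stop("segment '", s$name, "': missing cut_site", call. = FALSE)
    }
    if (!(s$start < s$end)) {
      stop("segment '", s$name, "': start must be < end", call. = FALSE)
    }
    if (s$cut_site < s$start || s$cut_site > s$end) {
      stop("segment '", s$name, "': cut_site outside [start, end]", call. = FALSE)
    }
    if (!s$strand %in% c("+", "-")) {
      stop("segment '", s$name, "': strand must be + or -", call. = FALSE)
    }
    if (s$role == "V") {
      if (!s$configuration %in% c("DEL", "INV")) {
        stop("segment '", s$name, "': V segment needs configuration DEL or INV",
             call. = FALSE)
      }
      # RSS lies 3' of the coding segment in segment orientation (V only; J
      # segments carry their RSS 5' of the coding flank).
      expected_rss <- if (s$strand == "+") "right" else "left"
      if (s$rss_side != expected_rss) {
        stop("segment '", s$name, "': rss_side '", s$rss_side,
             "' inconsistent with strand ", s$strand, call. = FALSE)
      }
    } else if (!is.na(s$configuration) && nzchar(s$configuration)) {
      stop("segment '", s$name, "': configuration defined only for role=V",
           call. = FALSE)
    }
  }

  stads <- spec$stads
  if (nrow(stads) > 0) {
    o <- order(stads$start)
    stads <- stads[o, ]
    if (any(stads$end[-nrow(stads)] > stads$start[-1])) {
      bad <- which(stads$end[-nrow(stads)] > stads$start[-1])[1]
      stop("sTADs '", stads$label[bad], "' and '", stads$label[bad + 1],
           "' overlap", call. = FALSE)
    }
    vseg <- seg[seg$role == "V", ]
    for (i in seq_len(nrow(vseg))) {
      s <- vseg[i, ]
      inside <- stads$start <= s$start & s$end <= stads$end
      if (sum(inside) != 1) {
        stop("V segment '", s$name, "' does not lie in exactly one sTAD",
             call. = FALSE)
      }
    }
  }

  baits <- spec$baits
  for (i in seq_len(nrow(baits))) {
    b <- baits[i, ]
    if (b$chrom != spec$locus$chrom) {
      stop("bait '", b$name, "': bait chromosome (", b$chrom,
           ") differs from locus chromosome (", spec$locus$chrom, ")",
           call. = FALSE)
    }
    if (!b$side %in% c("CE", "SE")) {
      stop("bait '", b$name, "': side must be CE or SE", call. = FALSE)
    }
    # Retained flank is on the primer side of the DSB; the read runs from the
    # primer toward the break (bait_strand is the read direction).
    if (b$bait_strand == "+") {
      if (!(b$primer_end - 1L <= b$dsb_coordinate)) {
        stop("bait '", b$name, "': primer interval not on the retained flank",
             call. = FALSE)
      }
    } else {
      if (!(b$primer_start > b$dsb_coordinate)) {
        stop("bait '", b$name, "': primer interval not on the retained flank",
             call. = FALSE)
      }
    }
  }
  spec
}

#' Strand-normalised offset of a position from a segment's cut site
#'
#' Returns `d = position - cut_site`, sign-flipped for minus-strand segments,
#' so that `d = 0` at the scission point, `d < 0` within the coding segment
#' body (sequence loss, i.e. resection into the segment), and `d > 0` on the
#' RSS/flank side -- regardless of segment orientation. Pooled coding- and
#' signal-end junctions from both strands therefore overlay on one axis.
#'
#' @param position 0-based genomic coordinate on the segment's chromosome.
#' @param segment one segment row of `spec$segments` (or an equivalent list
#'   with `cut_site` and `strand`).
#' @return signed integer offset in bp (vectorised over `position`).
#' @export
cut_site_offset <- function(position, segment) {
  d <- as.integer(position) - as.integer(segment$cut_site)
  if (segment$strand == "-") d <- -d
  d
}

#' Sub-TAD containing a position
#'
#' @param position 0-based genomic coordinate (vectorised).
#' @param spec a `locus_spec`.
#' @param chrom chromosome of `position` (default: the locus chromosome).
#' @return character vector of sTAD labels; `NA` outside all sTADs.
#' @export
stad_of <- function(position, spec, chrom = spec$locus$chrom) {
  out <- rep(NA_character_, length(position))
  if (!identical(chrom, spec$locus$chrom)) return(out)
  st <- spec$stads
  for (i in seq_len(nrow(st))) {
    hit <- position >= st$start[i] & position < st$end[i]
    out[hit] <- st$label[i]
  }
  out
}

segment_by_name <- function(spec, name) {
  i <- match(name, spec$segments$name)
  if (is.na(i)) stop("unknown segment: ", name, call. = FALSE)
  spec$segments[i, ]
}

bait_by_name <- function(spec, name) {
  i <- match(name, spec$baits$name)
  if (is.na(i)) stop("unknown bait: ", name, call. = FALSE)
  spec$baits[i, ]
}

#' The default toy antigen-receptor locus
#'
#' One 36 kb bait chromosome carrying twelve V segments (three per sub-TAD,
#' mixed deletional/inversional orientation) and one J segment with coding-end
#' and signal-end baits; two receptor-locus partner chromosomes and one
#' background chromosome for spontaneous translocation partners.
#'
#' @return a validated `locus_spec`.
#' @export
default_locus_spec <- function() {
  stads <- data.frame(
    label = c("sTAD1-2", "sTAD3", "sTAD4", "sTAD5"),
    chrom = "chrK",
    start = c(2000L, 9000L, 16000L, 23000L),
    end   = c(9000L, 16000L, 23000L, 29500L),
    stringsAsFactors = FALSE
  )
  v_start <- integer(0); v_strand <- character(0)
  for (i in seq_len(nrow(stads))) {
    v_start <- c(v_start, stads$start[i] + c(1000L, 3000L, 5000L))
    v_strand <- c(v_strand, c("+", "-", "+"))
  }
  vlen <- 300L
  segments <- data.frame(
    name = paste0("V", seq_along(v_start)),
    chrom = "chrK",
    start = v_start,
    end = v_start + vlen,
    strand = v_strand,
    role = "V",
    configuration = ifelse(v_strand == "+", "DEL", "INV"),
    cut_site = ifelse(v_strand == "+", v_start + vlen - 1L, v_start),
    rss_side = ifelse(v_strand == "+", "right", "left"),
    stringsAsFactors = FALSE
  )
  jseg <- data.frame(
    name = "J1", chrom = "chrK", start = 30500L, end = 30800L, strand = "+",
    role = "J", configuration = NA_character_, cut_site = 30500L,
    rss_side = "left", stringsAsFactors = FALSE
  )
  segments <- rbind(segments, jseg)

  baits <- data.frame(
    name = c("J1CE", "J1SE"),
    side = c("CE", "SE"),
    chrom = "chrK",
    # 0-based coordinate of the cut-adjacent retained base
    dsb_coordinate = c(30500L, 30499L),
    bait_strand = c("-", "+"),
    primer_start = c(30540L, 30440L),
    primer_end = c(30560L, 30460L),
    region_start = 30350L,
    region_end = 30650L,
    stringsAsFactors = FALSE
  )

  receptor_loci <- data.frame(
    label = c("recL", "recH"),
    chrom = c("chrL", "chrH"),
    start = 3000L,
    end = 3400L,
    stringsAsFactors = FALSE
  )

  new_locus_spec(
    segments = segments,
    baits = baits,
    stads = stads,
    locus = list(chrom = "chrK", start = 1000L, end = 33000L),
    receptor_loci = receptor_loci,
    chrom_lengths = c(chrK = 36000L, chrL = 8000L, chrH = 8000L, chrS = 15000L)
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat("<locus_spec> ", x$locus$chrom, ":", x$locus$start, "-", x$locus$end,
      "\n", sep = "")
  cat("  segments: ", sum(x$segments$role == "V"), " V, ",
      sum(x$segments$role == "J"), " J\n", sep = "")
  cat("  baits:    ", paste(x$baits$name, collapse = ", "), "\n", sep = "")
  cat("  sTADs:    ", paste(x$stads$label, collapse = ", "), "\n", sep = "")
  cat("  receptor loci: ", paste(x$receptor_loci$label, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
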