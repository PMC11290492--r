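#' Read a locus specification from BED + config files
#'
#' Segments are BED6 records whose name field encodes
#' `name|role|configuration|cut_site` (configuration empty for J segments;
#' `cut_site` is the 0-based coordinate of the cut-adjacent coding base).
#' Baits, sTAD boundaries, receptor loci, the locus interval and chromosome
#' lengths come from a flat YAML config.
#'
#' @param bed_file path to the BED6 segment annotation.
#' @param config_file path to the YAML locus config.
#' @return a validated `locus_spec`.
#' @export
load_locus_spec <- function(bed_file, config_file) {
  gr <- rtracklayer::import(bed_file, format = "BED")
  name_parts <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  get_part <- function(i) {
    vapply(name_parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  }
  cut_raw <- get_part(4)
  missing_cut <- is.na(cut_raw) | !nzchar(cut_raw)
  if (any(missing_cut)) {
    stop("segment '", get_part(1)[which(missing_cut)[1]],
         "': missing cut_site (expected name|role|configuration|cut_site)",
         call. = FALSE)
  }
  cut_site <- suppressWarnings(as.integer(cut_raw))
  if (anyNA(cut_site)) {
    stop("segment '", get_part(1)[which(is.na(cut_site))[1]],
         "': non-integer cut_site", call. = FALSE)
  }
  cfg_part <- get_part(3)
  cfg_part[is.na(cfg_part) | !nzchar(cfg_part)] <- NA_character_
  segments <- data.frame(
    name = get_part(1),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    role = get_part(2),
    configuration = cfg_part,
    cut_site = cut_site,
    rss_side = NA_character_,
    stringsAsFactors = FALSE
  )
  # rss_side is implied by orientation: 3' of the coding segment for V, 5' for J
  segments$rss_side <- ifelse(
    segments$role == "V",
    ifelse(segments$strand == "+", "right", "left"),
    ifelse(segments$strand == "+", "left", "right")
  )

  cfg <- yaml::read_yaml(config_file)
  req <- function(field) {
    if (is.null(cfg[[field]])) stop("config missing field: ", field, call. = FALSE)
    cfg[[field]]
  }
  baits <- do.call(rbind, lapply(req("baits"), function(b) {
    data.frame(name = b$name, side = b$side, chrom = b$chrom,
               dsb_coordinate = as.integer(b$dsb_coordinate),
               bait_strand = b$bait_strand,
               primer_start = as.integer(b$primer[1]),
               primer_end = as.integer(b$primer[2]),
               region_start = as.integer(b$region[1]),
               region_end = as.integer(b$region[2]),
               stringsAsFactors = FALSE)
  }))
  stads <- do.call(rbind, lapply(req("stads"), function(s) {
    data.frame(label = s$label, chrom = req("locus")$chrom,
               start = as.integer(s$start), end = as.integer(s$end),
               stringsAsFactors = FALSE)
  }))
  receptor_loci <- do.call(rbind, lapply(cfg$receptor_loci, function(r) {
    data.frame(label = r$label, chrom = r$chrom, start = as.integer(r$start),
               end = as.integer(r$end), stringsAsFactors = FALSE)
  }))
  if (is.null(receptor_loci)) {
    receptor_loci <- data.frame(label = character(0), chrom = character(0),
                                start = integer(0), end = integer(0))
  }
  lc <- req("locus")
  chrom_lengths <- unlist(req("chrom_lengths"))

  new_locus_spec(
    segments = segments, baits = baits, stads = stads,
    locus = list(chrom = lc$chrom, start = as.integer(lc$start),
                 end = as.integer(lc$end)),
    receptor_loci = receptor_loci,
    chrom_lengths = chrom_lengths
  )
}

#' Write a locus specification as BED + config files
#'
#' Inverse of [load_locus_spec()].
#'
#' @param spec a `locus_spec`.
#' @param bed_file,config_file output paths.
#' @return invisibly, the two paths.
#' @export
write_locus_spec <- function(spec, bed_file, config_file) {
  seg <- spec$segments
  cfgpart <- ifelse(is.na(seg$configuration), "", seg$configuration)
  bed <- data.frame(
    chrom = seg$chrom,
    start = seg$start,
    end = seg$end,
    name = paste(seg$name, seg$role, cfgpart, seg$cut_site, sep = "|"),
    score = 0L,
    strand = seg$strand
  )
  utils::write.table(bed, bed_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfg <- list(
    locus = list(chrom = spec$locus$chrom, start = spec$locus$start,
                 end = spec$locus$end),
    chrom_lengths = as.list(spec$chrom_lengths),
    baits = lapply(seq_len(nrow(spec$baits)), function(i) {
      b <- spec$baits[i, ]
      list(name = b$name, side = b$side, chrom = b$chrom,
           dsb_coordinate = b$dsb_coordinate, bait_strand = b$bait_strand,
           primer = c(b$primer_start, b$primer_end),
           region = c(b$region_start, b$region_end))
    }),
    stads = lapply(seq_len(nrow(spec$stads)), function(i) {
      s <- spec$stads[i, ]
      list(label = s$label, start = s$start, end = s$end)
    }),
    receptor_loci = lapply(seq_len(nrow(spec$receptor_loci)), function(i) {
      r <- spec$receptor_loci[i, ]
      list(label = r$label, chrom = r$chrom, start = r$start, end = r$end)
    })
  )
  yaml::write_yaml(cfg, config_file)
  invisible(c(bed_file, config_file))
}
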