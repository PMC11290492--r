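## tlx dialect: tab-delimited junction records, one line per junction-bearing
## read. Coordinates are 1-based inclusive. `Junction` is the strand-aware
## first prey base of the alignment (Rstart on '+', Rend on '-');
## `B_Junction` is the strand-aware last bait base. Columns beyond the
## mandatory set are carried through opaquely.

TLX_MANDATORY <- c("Qname", "JuncID", "Rname", "Junction", "Strand",
                   "Rstart", "Rend", "B_Rname", "B_Rstart", "B_Rend",
                   "B_Strand", "B_Junction", "B_Qstart", "B_Qend",
                   "Qstart", "Qend", "Qlen", "Seq")

TLX_INT_COLS <- c("JuncID", "Junction", "Rstart", "Rend", "B_Rstart", "B_Rend",
                  "B_Junction", "B_Qstart", "B_Qend", "Qstart", "Qend", "Qlen")

#' Read a tlx junction file
#'
#' Parses a tab-delimited tlx file and validates every record: all mandatory
#' columns present, integer coordinate fields, strands in `+`/`-`, and
#' `Rstart <= Rend` / `B_Rstart <= B_Rend`. Violations raise an error naming
#' the offending column and (1-based, header included) file line. Extra
#' columns are preserved untouched.
#'
#' @param file path to a tlx file.
#' @return data.frame of junction records.
#' @export
read_tlx <- function(file) {
  dt <- data.table::fread(file, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(TLX_MANDATORY, names(dt))
  if (length(missing_cols) > 0) {
    stop("tlx file ", file, ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line_of <- function(i) i + 1L  # header is line 1
  for (col in TLX_INT_COLS) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) | v != suppressWarnings(as.numeric(dt[[col]])))
    if (length(bad) > 0) {
      stop("tlx file ", file, " line ", line_of(bad[1]), ": column '", col,
           "' is not an integer (value '", dt[[col]][bad[1]], "')",
           call. = FALSE)
    }
    dt[[col]] <- v
  }
  for (col in c("Strand", "B_Strand")) {
    bad <- which(!dt[[col]] %in% c("+", "-"))
    if (length(bad) > 0) {
      stop("tlx file ", file, " line ", line_of(bad[1]), ": column '", col,
           "' must be '+' or '-' (value '", dt[[col]][bad[1]], "')",
           call. = FALSE)
    }
  }
  bad <- which(dt$Rstart > dt$Rend)
  if (length(bad) > 0) {
    stop("tlx file ", file, " line ", line_of(bad[1]),
         ": Rstart > Rend", call. = FALSE)
  }
  bad <- which(dt$B_Rstart > dt$B_Rend)
  if (length(bad) > 0) {
    stop("tlx file ", file, " line ", line_of(bad[1]),
         ": B_Rstart > B_Rend", call. = FALSE)
  }
  dt
}

#' Write a tlx junction file
#'
#' Inverse of [read_tlx()]; a read/write cycle is byte-identical for files
#' produced by this writer.
#'
#' @param tlx data.frame of junction records.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_tlx <- function(tlx, file) {
  extra <- setdiff(names(tlx), TLX_MANDATORY)
  tlx <- tlx[, c(TLX_MANDATORY, extra), drop = FALSE]
  data.table::fwrite(tlx, file, sep = "\t", quote = FALSE, eol = "\n")
  invisible(file)
}

#' Junction density as a bedGraph track
#'
#' One interval per distinct junction base (width 1, 0-based half-open as per
#' bedGraph) whose value is the number of junction records at that base. The
#' sum of all values equals the number of input records (conservation).
#'
#' @param tlx data.frame of junction records.
#' @return data.frame with `chrom`, `start`, `end`, `value`, sorted by
#'   chromosome then start.
#' @export
tlx_to_bedgraph <- function(tlx) {
  if (nrow(tlx) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = integer(0)))
  }
  dt <- data.table::data.table(chrom = tlx$Rname, start = tlx$Junction - 1L)
  agg <- dt[, list(value = .N), by = c("chrom", "start")]
  data.table::setorderv(agg, c("chrom", "start"))
  out <- as.data.frame(agg)
  out$end <- out$start + 1L
  out[, c("chrom", "start", "end", "value")]
}

#' Write / read a bedGraph track
#'
#' Plain four-column bedGraph without a track line; `read_bedgraph` inverts
#' `write_bedgraph` exactly.
#'
#' @param bg data.frame with `chrom`, `start`, `end`, `value`.
#' @param file path.
#' @return `write_bedgraph`: the path, invisibly; `read_bedgraph`: the
#'   data.frame.
#' @export
write_bedgraph <- function(bg, file) {
  utils::write.table(bg[, c("chrom", "start", "end", "value")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  score <- gr$score
  if (all(score == round(score))) score <- as.integer(score)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = score,
             stringsAsFactors = FALSE)
}

#' Intersect junctions with genomic regions
#'
#' Keeps the records whose junction point falls inside any of the given
#' 0-based half-open regions, annotating each with the (first) matching
#' region's name. A record is counted once even when regions overlap.
#'
#' @param tlx data.frame of junction records.
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open).
#' @return the matching tlx rows with an added `region` column.
#' @export
intersect_regions <- function(tlx, regions) {
  if (nrow(tlx) == 0 || nrow(regions) == 0) {
    out <- tlx[integer(0), , drop = FALSE]
    out$region <- character(0)
    return(out)
  }
  if (is.null(regions$name)) regions$name <- paste0("region", seq_len(nrow(regions)))
  qry <- GenomicRanges::GRanges(tlx$Rname,
                                IRanges::IRanges(tlx$Junction, width = 1L))
  sub <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(regions$start + 1L,
                                                 regions$end))
  ov <- GenomicRanges::findOverlaps(qry, sub, select = "first")
  keep <- which(!is.na(ov))
  out <- tlx[keep, , drop = FALSE]
  out$region <- regions$name[ov[keep]]
  out
}

#' Junction extraction windows around segment cut sites
#'
#' One window per segment of the requested role, spanning `pad` bp on each
#' side of the cut site (`[cut - pad, cut + pad]` inclusive, returned 0-based
#' half-open).
#'
#' @param spec a `locus_spec`.
#' @param pad window half-width in bp (default 200).
#' @param role segment role(s) to include.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
regions_around_cut_sites <- function(spec, pad = 200L, role = "V") {
  seg <- spec$segments[spec$segments$role %in% role, ]
  data.frame(chrom = seg$chrom,
             start = seg$cut_site - as.integer(pad),
             end = seg$cut_site + as.integer(pad) + 1L,
             name = seg$name,
             stringsAsFactors = FALSE)
}
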