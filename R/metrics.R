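## Library-level metrics over classified junctions.

#' Downsample identifiers to a normalisation depth
#'
#' @param ids vector of read/junction identifiers.
#' @param n target depth (default 500000).
#' @param seed seed for the draw.
#' @return sampled ids; all of them (with a warning) when fewer than `n` are
#'   available.
#' @export
downsample <- function(ids, n = 500000L, seed = 1L) {
  if (length(ids) <= n) {
    if (length(ids) < n) {
      warning("only ", length(ids), " identifiers available for a depth of ",
              n, "; using all of them", call. = FALSE)
    }
    return(ids)
  }
  with_seed(seed, sample(ids, n))
}

#' V(D)J joining efficiency
#'
#' V-region junction count divided by the total read count the library was
#' normalised to.
#'
#' @param classified output of [classify_junctions()].
#' @param total_reads normalisation denominator (total reads in the library).
#' @return efficiency in [0, 1]; 0 when there are no V-J junctions; errors on
#'   a zero denominator.
#' @export
vj_efficiency <- function(classified, total_reads) {
  if (total_reads <= 0) {
    stop("total_reads must be positive to compute a joining efficiency",
         call. = FALSE)
  }
  sum(classified$category == "V_J") / total_reads
}

#' Coding-end / signal-end usage of V-region junctions
#'
#' @param classified output of [classify_junctions()].
#' @return list with `ce_count`, `se_count` and `ratio` (`NA` when the
#'   signal-end count is 0: the ratio is undefined, not infinite).
#' @export
ce_se_ratio <- function(classified) {
  v <- classified[classified$category == "V_J", ]
  ce <- sum(v$prey_end_type == "CE", na.rm = TRUE)
  se <- sum(v$prey_end_type == "SE", na.rm = TRUE)
  list(ce_count = ce, se_count = se,
       ratio = if (se == 0) NA_real_ else ce / se)
}

#' Joint structure distribution over the MH/direct/insertion axis
#'
#' Counts junctions of the requested scope into the 41-bin axis
#' `MH20..MH1, direct, INS1..INS20` and reports the MMEJ fraction
#' (microhomology length > 1 bp, the operational MMEJ definition).
#'
#' @param classified output of [classify_junctions()].
#' @param scope `"V_region"` (V-J junctions) or `"translocation"`.
#' @return list with `counts` (named 41-vector), `n`, `mmej_fraction`,
#'   `direct_fraction`, `n_out_of_range`.
#' @export
structure_distribution <- function(classified,
                                   scope = c("V_region", "translocation")) {
  scope <- match.arg(scope)
  sel <- if (scope == "V_region") classified$category == "V_J"
         else classified$category == "translocation"
  x <- classified[sel, ]
  x <- x[!x$out_of_range, ]
  bin <- ifelse(x$structure_kind == "direct", "direct",
                ifelse(x$structure_kind == "MH",
                       paste0("MH", x$structure_length),
                       paste0("INS", x$structure_length)))
  counts <- stats::setNames(integer(41), structure_bin_names())
  tab <- table(bin)
  counts[names(tab)] <- as.integer(tab)
  n <- sum(counts)
  mmej <- sum(x$structure_kind == "MH" & x$structure_length > 1L)
  list(counts = counts, n = n,
       mmej_fraction = if (n > 0) mmej / n else NA_real_,
       direct_fraction = if (n > 0) counts[["direct"]] / n else NA_real_,
       n_out_of_range = sum(sel) - n)
}

#' Resection enrichment near V cut sites
#'
#' Fraction of V-J junctions within `w_inner` bp of their assigned cut site
#' among those within `w_outer` bp, computed from the strand-normalised
#' resection offsets: `N(|d| <= w_inner) / N(|d| <= w_outer)`. Equals 1
#' exactly when every junction sits at offset 0 (no resection).
#'
#' @param classified output of [classify_junctions()].
#' @param w_inner,w_outer window half-widths in bp (defaults 10 and 100).
#' @return list with `enrichment` (`NA` and reported when the outer window is
#'   empty), `n_inner`, `n_window`.
#' @export
resection_enrichment <- function(classified, w_inner = 10L, w_outer = 100L) {
  offs <- classified$resection_offset[classified$category == "V_J"]
  offs <- offs[!is.na(offs) & abs(offs) <= w_outer]
  n_window <- length(offs)
  n_inner <- sum(abs(offs) <= w_inner)
  enr <- if (n_window == 0) NA_real_ else n_inner / n_window
  list(enrichment = enr, n_inner = n_inner, n_window = n_window)
}

#' V-J junction distribution over sub-TADs
#'
#' @param classified output of [classify_junctions()].
#' @param spec a `locus_spec`.
#' @return data.frame with `stad`, `count`, `fraction` (one row per sTAD, in
#'   spec order).
#' @export
stad_distribution <- function(classified, spec) {
  v <- classified[classified$category == "V_J" & !is.na(classified$stad), ]
  counts <- vapply(spec$stads$label, function(l) sum(v$stad == l), 1L)
  n <- sum(counts)
  data.frame(stad = spec$stads$label,
             count = as.integer(counts),
             fraction = if (n > 0) counts / n else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE)
}

#' Translocation frequency
#'
#' Relative mode: translocation junction count scaled to events per 500,000
#' library reads, without deduplication. Absolute mode: distinct junctions
#' after deduplication on (`Rname`, `Strand`, `Junction`, `B_Junction`), i.e.
#' exact amplification duplicates collapse to one event.
#'
#' @param classified output of [classify_junctions()].
#' @param total_reads library size used for the relative scaling.
#' @param mode `"relative"` or `"absolute"`.
#' @return list with `frequency`, `n`, and `by_class` (named counts over
#'   `receptor_locus` / `spontaneous`, same mode).
#' @export
translocation_frequency <- function(classified, total_reads,
                                    mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  tr <- classified[classified$category == "translocation", ]
  if (mode == "absolute") {
    key <- paste(tr$Rname, tr$Strand, tr$Junction, tr$B_Junction, sep = "\r")
    keep <- !duplicated(key)
    tr <- tr[keep, ]
    n <- nrow(tr)
    freq <- n
  } else {
    n <- nrow(tr)
    if (total_reads <= 0) stop("total_reads must be positive", call. = FALSE)
    freq <- n * 500000 / total_reads
  }
  by_class <- vapply(c("receptor_locus", "spontaneous"), function(cl) {
    sum(tr$translocation_class == cl, na.rm = TRUE)
  }, 1L)
  scale <- if (mode == "relative") 500000 / total_reads else 1
  list(frequency = freq, n = n, by_class = by_class * scale)
}

#' Compute the full metrics panel
#'
#' @param classified output of [classify_junctions()].
#' @param spec a `locus_spec`.
#' @param total_reads total library read count (the efficiency and relative
#'   translocation denominators).
#' @return a `metrics_table` list.
#' @export
compute_metrics <- function(classified, spec, total_reads) {
  structure(list(
    total_reads = total_reads,
    n_junctions = nrow(classified),
    category_counts = table(classified$category),
    vj_efficiency = vj_efficiency(classified, total_reads),
    ce_se = ce_se_ratio(classified),
    structure_v = structure_distribution(classified, "V_region"),
    resection = resection_enrichment(classified),
    stads = stad_distribution(classified, spec),
    transloc_relative = translocation_frequency(classified, total_reads,
                                                "relative"),
    transloc_absolute = translocation_frequency(classified, total_reads,
                                                "absolute")
  ), class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("<metrics_table> ", x$n_junctions, " junctions / ", x$total_reads,
      " reads\n", sep = "")
  cat("  categories:  ",
      paste(names(x$category_counts), as.integer(x$category_counts),
            sep = "=", collapse = " "), "\n", sep = "")
  cat("  V-J efficiency: ", signif(x$vj_efficiency, 4), "\n", sep = "")
  cat("  CE/SE: ", x$ce_se$ce_count, "/", x$ce_se$se_count, " (ratio ",
      signif(x$ce_se$ratio, 4), ")\n", sep = "")
  cat("  V-region structure: direct ",
      signif(x$structure_v$direct_fraction, 4), ", MMEJ ",
      signif(x$structure_v$mmej_fraction, 4), " of n=", x$structure_v$n,
      "\n", sep = "")
  cat("  resection enrichment (|d|<=10 / |d|<=100): ",
      signif(x$resection$enrichment, 4), "\n", sep = "")
  cat("  sTAD fractions: ",
      paste(x$stads$stad, signif(x$stads$fraction, 3), sep = "=",
            collapse = " "), "\n", sep = "")
  cat("  translocations: relative ", signif(x$transloc_relative$frequency, 4),
      " per 500k, absolute ", x$transloc_absolute$frequency, "\n", sep = "")
  invisible(x)
}

#' Write the metrics panel as tab-delimited tables
#'
#' Writes a flat `key\tvalue` summary plus the structure histogram and sTAD
#' table, all as plain text.
#'
#' @param m a `metrics_table`.
#' @param prefix output path prefix; files `<prefix>_summary.tsv`,
#'   `<prefix>_structure.tsv`, `<prefix>_stads.tsv` are written.
#' @return invisibly, the written paths.
#' @export
write_metrics <- function(m, prefix) {
  summary_df <- data.frame(
    key = c("total_reads", "n_junctions", "vj_efficiency", "ce_count",
            "se_count", "ce_se_ratio", "direct_fraction", "mmej_fraction",
            "resection_enrichment", "transloc_relative_per500k",
            "transloc_absolute"),
    value = c(m$total_reads, m$n_junctions, m$vj_efficiency,
              m$ce_se$ce_count, m$ce_se$se_count, m$ce_se$ratio,
              m$structure_v$direct_fraction, m$structure_v$mmej_fraction,
              m$resection$enrichment, m$transloc_relative$frequency,
              m$transloc_absolute$frequency)
  )
  f1 <- paste0(prefix, "_summary.tsv")
  utils::write.table(summary_df, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure_df <- data.frame(bin = names(m$structure_v$counts),
                             count = as.integer(m$structure_v$counts))
  f2 <- paste0(prefix, "_structure.tsv")
  utils::write.table(structure_df, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f3 <- paste0(prefix, "_stads.tsv")
  utils::write.table(m$stads, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
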