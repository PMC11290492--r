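#' Junction-coordinate concordance between two tlx collections
#'
#' Matches records by `Qname` and compares junction coordinates
#' (`Rname`, `Junction`, `Strand`). Every discordance is returned with a
#' reason: `missing_call` (in truth only), `extra_call` (called only),
#' `wrong_chrom`, `wrong_strand`, or `junction_shift` (same chromosome and
#' strand, coordinate moved; the shift in bp is reported).
#'
#' @param truth_tlx reference tlx records (e.g. [emit_truth_tlx()]).
#' @param called_tlx tlx records under test.
#' @return list with `concordance` (fraction of truth records exactly
#'   recovered), `n_truth`, `n_called`, and `discordances` (data.frame with
#'   `Qname`, `reason`, `shift`).
#' @export
junction_concordance <- function(truth_tlx, called_tlx) {
  key <- c("Rname", "Junction", "Strand")
  m <- merge(truth_tlx[, c("Qname", key)], called_tlx[, c("Qname", key)],
             by = "Qname", suffixes = c(".t", ".c"), all = TRUE)
  in_t <- !is.na(m$Rname.t)
  in_c <- !is.na(m$Rname.c)
  reason <- rep(NA_character_, nrow(m))
  shift <- rep(NA_integer_, nrow(m))
  reason[in_t & !in_c] <- "missing_call"
  reason[!in_t & in_c] <- "extra_call"
  both <- in_t & in_c
  reason[both & m$Rname.t != m$Rname.c] <- "wrong_chrom"
  sel <- both & m$Rname.t == m$Rname.c & m$Strand.t != m$Strand.c
  reason[sel] <- "wrong_strand"
  sel <- both & m$Rname.t == m$Rname.c & m$Strand.t == m$Strand.c &
    m$Junction.t != m$Junction.c
  reason[sel] <- "junction_shift"
  shift[sel] <- m$Junction.c[sel] - m$Junction.t[sel]
  disc <- data.frame(Qname = m$Qname, reason = reason, shift = shift,
                     stringsAsFactors = FALSE)
  disc <- disc[!is.na(disc$reason), , drop = FALSE]
  n_truth <- sum(in_t)
  concord <- sum(both & is.na(reason)) / max(n_truth, 1L)
  list(concordance = concord, n_truth = n_truth, n_called = sum(in_c),
       discordances = disc)
}
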