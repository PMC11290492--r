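#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_library()]. The defaults
#' describe a G0/G1-arrested, Ku-deficient (alternative end joining) library:
#' a dominant direct-joint peak (~55%) with exponentially decaying
#' microhomology use over 1-4 bp, a coding-end bait with roughly one hybrid
#' (CE-SE) joint per two cognate joints (CE/SE ratio ~2), per-end resection
#' modelled as a point mass at 0 plus a truncated geometric tail, V usage
#' declining with distance from the J-proximal sub-TAD, and translocations to
#' both other antigen-receptor loci and spontaneous break sites.
#'
#' @param n_read_pairs number of read pairs to simulate (one junction-bearing
#'   read per pair is emitted).
#' @param seed integer seed controlling every random choice.
#' @param regime `"AEJ"`, `"NHEJ"` or `"MMEJ_dominant"`; sets regime-typical
#'   defaults for the structure weights, hybrid rate and resection mixture,
#'   all of which can still be overridden explicitly.
#' @param bait name of the bait in the locus spec the library is anchored on.
#' @param vj_rate probability a read pair carries a V-J joint.
#' @param rejoin_rate probability of a rejoin of the bait DSB.
#' @param translocation_rate probability of a translocation; the remainder of
#'   the event space is unjoined (bait-only) reads.
#' @param translocation_split named proportions over
#'   `c(receptor_locus=, spontaneous=)`.
#' @param hybrid_rate probability that a V-J prey contributes its non-cognate
#'   end (a CE bait joined to a signal end, or vice versa).
#' @param v_usage named per-sTAD weights for V-segment choice.
#' @param structure_weights named weights over `direct`, `MH1`..`MH20`,
#'   `INS1`..`INS20` (missing names get weight 0).
#' @param palindromic_insertion_rate probability an insertion of length <= 4
#'   from a coding-end bait is palindromic (a P-nucleotide-like reverse
#'   complement of the bait-proximal flank).
#' @param resection_w0 weight of the point mass at 0 bp in the per-end
#'   resection mixture.
#' @param resection_mean mean (bp) of the geometric resection tail.
#' @param resection_max truncation (bp) of the resection tail; must be <= 200,
#'   the V-region junction extraction window.
#' @param error_rate per-base substitution probability.
#' @param read_length read length in bp.
#' @param duplicate_rate probability a read is emitted twice (exact duplicate;
#'   exists to exercise deduplication).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_read_pairs = 50000L,
                       seed = 1L,
                       regime = c("AEJ", "NHEJ", "MMEJ_dominant"),
                       bait = "J1CE",
                       vj_rate = 0.04,
                       rejoin_rate = 0.5,
                       translocation_rate = 0.004,
                       translocation_split = c(receptor_locus = 0.6,
                                               spontaneous = 0.4),
                       hybrid_rate = NULL,
                       v_usage = c("sTAD1-2" = 0.18, "sTAD3" = 0.20,
                                   "sTAD4" = 0.24, "sTAD5" = 0.38),
                       structure_weights = NULL,
                       palindromic_insertion_rate = 0.25,
                       resection_w0 = NULL,
                       resection_mean = NULL,
                       resection_max = 100L,
                       error_rate = 0.001,
                       read_length = 150L,
                       duplicate_rate = 0) {
  regime <- match.arg(regime)
  preset <- regime_preset(regime)
  if (is.null(hybrid_rate)) hybrid_rate <- preset$hybrid_rate
  if (is.null(structure_weights)) structure_weights <- preset$structure_weights
  if (is.null(resection_w0)) resection_w0 <- preset$resection_w0
  if (is.null(resection_mean)) resection_mean <- preset$resection_mean

  cfg <- structure(list(
    n_read_pairs = as.integer(n_read_pairs),
    seed = as.integer(seed),
    regime = regime,
    bait = bait,
    vj_rate = vj_rate,
    rejoin_rate = rejoin_rate,
    translocation_rate = translocation_rate,
    translocation_split = translocation_split,
    hybrid_rate = hybrid_rate,
    v_usage = v_usage,
    structure_weights = normalize_structure_weights(structure_weights),
    palindromic_insertion_rate = palindromic_insertion_rate,
    resection_w0 = resection_w0,
    resection_mean = resection_mean,
    resection_max = as.integer(resection_max),
    error_rate = error_rate,
    read_length = as.integer(read_length),
    duplicate_rate = duplicate_rate
  ), class = "sim_config")
  validate_sim_config(cfg)
}

regime_preset <- function(regime) {
  switch(regime,
    AEJ = list(
      structure_weights = c(direct = 0.55, MH1 = 0.25, MH2 = 0.12,
                            MH3 = 0.06, MH4 = 0.02),
      hybrid_rate = 1 / 3,
      resection_w0 = 0.8, resection_mean = 30
    ),
    NHEJ = list(
      structure_weights = c(direct = 0.70, MH1 = 0.10, MH2 = 0.03, MH3 = 0.01,
                            INS1 = 0.06, INS2 = 0.05, INS3 = 0.03, INS4 = 0.02),
      hybrid_rate = 1 / 850,
      resection_w0 = 0.95, resection_mean = 5
    ),
    MMEJ_dominant = list(
      structure_weights = c(direct = 0.18, MH1 = 0.22, MH2 = 0.25, MH3 = 0.18,
                            MH4 = 0.10, MH5 = 0.05, MH6 = 0.02),
      hybrid_rate = 0.45,
      resection_w0 = 0.5, resection_mean = 40
    )
  )
}

structure_bin_names <- function() {
  c(paste0("MH", 20:1), "direct", paste0("INS", 1:20))
}

normalize_structure_weights <- function(w) {
  full <- stats::setNames(numeric(41), structure_bin_names())
  unknown <- setdiff(names(w), names(full))
  if (length(unknown) > 0) {
    stop("unknown structure weight names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full[names(w)] <- w
  full
}

validate_sim_config <- function(cfg) {
  check_prob_vec <- function(x, nm) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
      stop(nm, " must be non-negative and sum to 1 (got sum ", sum(x), ")",
           call. = FALSE)
    }
  }
  ev <- c(cfg$vj_rate, cfg$rejoin_rate, cfg$translocation_rate)
  if (any(ev < 0) || sum(ev) > 1 + 1e-9) {
    stop("vj_rate + rejoin_rate + translocation_rate must be <= 1",
         call. = FALSE)
  }
  check_prob_vec(cfg$translocation_split, "translocation_split")
  check_prob_vec(cfg$structure_weights, "structure_weights")
  check_prob_vec(cfg$v_usage, "v_usage")
  if (cfg$resection_w0 < 0 || cfg$resection_w0 > 1) {
    stop("resection_w0 must be in [0, 1]", call. = FALSE)
  }
  if (cfg$resection_max > 200L) {
    stop("resection_max must be <= 200 (the V-region extraction window)",
         call. = FALSE)
  }
  if (cfg$hybrid_rate < 0 || cfg$hybrid_rate > 1) {
    stop("hybrid_rate must be in [0, 1]", call. = FALSE)
  }
  cfg
}

#' Per-end resection mixture probabilities
#'
#' The per-end resection model is a point mass at 0 bp (weight `w0`) plus a
#' geometric tail with mean `mu` bp on 1..`l_max` (renormalised after
#' truncation). `resection_pmf` returns P(R = r) for r = 0..`l_max`;
#' `resection_cdf` returns P(R <= x).
#'
#' @param w0 weight of the point mass at zero.
#' @param mu mean of the (untruncated) geometric tail.
#' @param l_max truncation bound in bp.
#' @param x non-negative value(s) at which to evaluate the CDF.
#' @return numeric vector of probabilities.
#' @export
resection_pmf <- function(w0, mu, l_max) {
  p <- 1 / mu
  tail <- stats::dgeom(0:(l_max - 1L), p)
  tail <- tail / sum(tail)
  c(w0, (1 - w0) * tail)
}

#' @rdname resection_pmf
#' @export
resection_cdf <- function(x, w0, mu, l_max) {
  pmf <- resection_pmf(w0, mu, l_max)
  cdf <- cumsum(pmf)
  ix <- pmin(pmax(floor(x), -1), l_max) + 1L
  out <- numeric(length(x))
  out[ix >= 1L] <- cdf[ix[ix >= 1L]]
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> regime=", x$regime, " bait=", x$bait,
      " n=", x$n_read_pairs, " seed=", x$seed, "\n", sep = "")
  cat("  events: V-J ", x$vj_rate, ", rejoin ", x$rejoin_rate,
      ", translocation ", x$translocation_rate, ", hybrid ",
      signif(x$hybrid_rate, 3), "\n", sep = "")
  w <- x$structure_weights[x$structure_weights > 0]
  cat("  structure: ", paste0(names(w), "=", w, collapse = " "), "\n", sep = "")
  cat("  resection: w0=", x$resection_w0, " mean=", x$resection_mean,
      " max=", x$resection_max, "; error_rate=", x$error_rate,
      " read_length=", x$read_length, "\n", sep = "")
  invisible(x)
}
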