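# Quantifying loss of the tissue-unique methylation signature:
# low/high-fibrosis group comparison, concordance with the direction of
# the cross-tissue common baseline, an exact log-space sign test, overlap
# enrichment, and the uniqueness-vs-correlation relation.

#' Group-wise drift of unique sites across a fibrosis threshold
#'
#' For each called probe, compares its mean beta in samples with
#' interstitial fibrosis below the threshold against samples above it
#' (samples exactly at the threshold are excluded), and flags whether the
#' change points toward the cross-tissue common baseline:
#' `toward_common = sign(mean_high - mean_low) == sign(baseline - mean_low)`.
#'
#' @param matrix Probes x samples cohort beta matrix.
#' @param sheet Sample sheet with an `IF` column (percent fibrosis).
#' @param calls Data frame from [call_unique_sites()]; its probes define
#'   the rows analyzed and the `baseline` is the pooled non-target median
#'   (`target_mean + uniqueness`).
#' @param if_threshold Fibrosis cut point in percent (default 20).
#' @return A data frame with one row per called probe present in the
#'   cohort: `probe_id`, `mean_low`, `mean_high`, `baseline`,
#'   `toward_common` (logical, `NA` when the change or the gap to baseline
#'   is exactly zero).
#' @export
group_drift <- function(matrix, sheet, calls, if_threshold = 20) {
  al <- align_samples(matrix, sheet)
  ifv <- al$sheet$IF
  low  <- !is.na(ifv) & ifv < if_threshold
  high <- !is.na(ifv) & ifv > if_threshold
  if (sum(low) < 3L || sum(high) < 3L) {
    stop("need >= 3 samples on each side of IF = ", if_threshold,
         " (have ", sum(low), " below, ", sum(high), " above)")
  }
  probes <- intersect(calls$probe_id, rownames(al$matrix))
  if (length(probes) == 0L) stop("no called probe present in the cohort")
  m <- al$matrix[probes, , drop = FALSE]
  mean_low  <- rowMeans(m[, low, drop = FALSE], na.rm = TRUE)
  mean_high <- rowMeans(m[, high, drop = FALSE], na.rm = TRUE)
  baseline <- calls$target_mean + calls$uniqueness
  baseline <- baseline[match(probes, calls$probe_id)]
  d_obs  <- mean_high - mean_low
  d_base <- baseline - mean_low
  toward <- ifelse(d_obs == 0 | d_base == 0, NA,
                   sign(d_obs) == sign(d_base))
  out <- data.frame(
    probe_id = probes,
    mean_low = mean_low,
    mean_high = mean_high,
    baseline = baseline,
    toward_common = toward,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "group_sizes") <- c(low = sum(low), high = sum(high))
  out
}

#' Exact one-sided sign test, in log space
#'
#' The probability of observing at least `k_toward` concordant outcomes
#' out of `n` under a fair coin: `P(X >= k)`, `X ~ Binomial(n, 1/2)`.
#' Computed in log space so that tails far below double-precision
#' underflow (e.g. all of several hundred sites concordant) remain
#' representable through `log10_p`.
#'
#' @param k_toward Number of concordant outcomes.
#' @param n Number of informative outcomes (>= 1).
#' @return A list with `p` (linear scale; 0 when underflowed) and
#'   `log10_p`.
#' @examples
#' sign_test(289, 289)$log10_p  # ~ -87.0
#' sign_test(8, 10)$p           # 56/1024
#' @export
sign_test <- function(k_toward, n) {
  stopifnot(n >= 1, k_toward >= 0, k_toward <= n)
  log_p <- stats::pbinom(k_toward - 1, size = n, prob = 0.5,
                         lower.tail = FALSE, log.p = TRUE)
  list(p = exp(log_p), log10_p = log_p / log(10))
}

#' Hypergeometric overlap enrichment of two probe sets
#'
#' Tests whether the overlap of two probe sets within a common universe
#' exceeds chance: `expected = |A| * |B| / |U|` and the upper-tail
#' hypergeometric probability `P(X >= observed)`, computed in log space.
#'
#' @param set_a,set_b Character vectors of probe ids, subsets of
#'   `universe`.
#' @param universe Character vector of all probe ids considered.
#' @return A list with `observed`, `expected`, `p` (linear), `log10_p`,
#'   `universe`, `set_a`, `set_b` (sizes).
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of the universe")
  }
  observed <- length(intersect(set_a, set_b))
  expected <- length(set_a) * length(set_b) / length(universe)
  log_p <- stats::phyper(observed - 1, m = length(set_a),
                         n = length(universe) - length(set_a),
                         k = length(set_b),
                         lower.tail = FALSE, log.p = TRUE)
  list(observed = observed, expected = expected,
       p = exp(log_p), log10_p = log_p / log(10),
       universe = length(universe), set_a = length(set_a),
       set_b = length(set_b))
}

#' Correlation between site uniqueness and correlation-to-fibrosis
#'
#' Pearson correlation, across called unique sites, between the signed
#' uniqueness distance and the signed per-probe correlation with the
#' fibrosis score — positive when the most distinctive sites are also the
#' ones whose methylation tracks fibrosis most strongly.
#'
#' @param calls Data frame from [call_unique_sites()].
#' @param scan Data frame from [pearson_scan()] against IF.
#' @return A list with `r`, `n` (shared probes), `t`, `p`, `log10_p`.
#' @export
uniqueness_vs_if <- function(calls, scan) {
  shared <- intersect(calls$probe_id, scan$probe_id)
  if (length(shared) < 3L) {
    stop("need >= 3 probes shared between calls and scan, have ",
         length(shared))
  }
  u <- calls$uniqueness[match(shared, calls$probe_id)]
  r_if <- scan$r[match(shared, scan$probe_id)]
  if (stats::sd(u) == 0 || stats::sd(r_if) == 0) {
    stop("uniqueness or correlation values are constant; ",
         "correlation undefined")
  }
  r <- stats::cor(u, r_if)
  tp <- t_and_p(r, length(shared))
  log10_p <- if (tp$exact_fit) -Inf else {
    log_p <- log(2) + stats::pt(-abs(tp$t), df = length(shared) - 2,
                                log.p = TRUE)
    log_p / log(10)
  }
  list(r = r, n = length(shared), t = tp$t, p = tp$p, log10_p = log10_p)
}
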