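# Tissue-unique CpG site calling from a multi-tissue methylation atlas.
#
# A probe is called unique in the target tissue when its mean beta there
# lies at least `delta` below the q-quantile (under) or at least `delta`
# above the (1-q)-quantile (over) of all non-target samples pooled. Probes
# with too few non-missing values across the atlas are removed first.

#' Call tissue-unique CpG sites
#'
#' Applies the quantile-offset rule: a probe is unique-under when its mean
#' beta in the target tissue is lower by at least `delta` than the `q`
#' quantile of all other samples, and unique-over when it is higher by at
#' least `delta` than the `1 - q` quantile. Quantiles are computed over
#' the pooled non-target samples (type-7 linear interpolation); a
#' per-tissue-mean mode is available for sensitivity analysis. Probes with
#' fewer than `min_values` non-missing values across the whole atlas are
#' excluded before calling.
#'
#' @param atlas A [tissue_atlas()].
#' @param target_tissue Tissue label to test for uniqueness (e.g.
#'   `"kidney"`).
#' @param delta Offset beyond the quantile, in beta units (default 0.2).
#' @param q Tail fraction in (0, 0.5) (default 0.05).
#' @param min_values Minimum non-missing values per probe across the atlas.
#'   The default, `NULL`, uses 2000 when the atlas has at least 2000
#'   samples (the scale of public multi-tissue references) and
#'   `ceiling(0.7 * n_samples)` otherwise.
#' @param per_tissue_quantiles If `TRUE`, quantiles are taken over the
#'   per-tissue means of the non-target tissues instead of the pooled
#'   samples.
#' @return A data frame with one row per called probe: `probe_id`,
#'   `direction` (`"under"`/`"over"`), `target_mean`, `other_q_low`,
#'   `other_q_high`, `gap` (margin beyond the threshold), `uniqueness`
#'   (signed distance, see [uniqueness_score()]) and `n_values`.
#' @export
call_unique_sites <- function(atlas, target_tissue, delta = 0.2, q = 0.05,
                              min_values = NULL,
                              per_tissue_quantiles = FALSE) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  if (delta < 0) stop("delta must be non-negative")
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)")
  tissues <- atlas$tissues
  if (!target_tissue %in% tissues) {
    stop("target tissue '", target_tissue, "' not present in the atlas")
  }
  m <- atlas$matrix
  is_target <- tissues == target_tissue
  if (sum(!is_target) < 2L) stop("need at least 2 non-target samples")
  if (is.null(min_values)) {
    min_values <- if (ncol(m) >= 2000) 2000 else ceiling(0.7 * ncol(m))
  }

  n_values <- rowSums(!is.na(m))
  keep <- n_values >= min_values
  m <- m[keep, , drop = FALSE]
  n_values <- n_values[keep]

  target_mean <- rowMeans(m[, is_target, drop = FALSE], na.rm = TRUE)
  other <- m[, !is_target, drop = FALSE]
  if (per_tissue_quantiles) {
    other_t <- tissues[!is_target]
    per_tissue <- vapply(unique(other_t), function(tt) {
      rowMeans(other[, other_t == tt, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(other)))
    qs <- t(apply(per_tissue, 1L, stats::quantile,
                  probs = c(q, 1 - q), na.rm = TRUE, names = FALSE))
  } else {
    qs <- t(apply(other, 1L, stats::quantile,
                  probs = c(q, 1 - q), na.rm = TRUE, names = FALSE))
  }
  q_low <- qs[, 1L]
  q_high <- qs[, 2L]
  other_median <- apply(other, 1L, stats::median, na.rm = TRUE)

  under <- !is.na(target_mean) & target_mean <= q_low - delta
  over  <- !is.na(target_mean) & target_mean >= q_high + delta
  called <- under | over
  out <- data.frame(
    probe_id = rownames(m)[called],
    direction = ifelse(under[called], "under", "over"),
    target_mean = target_mean[called],
    other_q_low = q_low[called],
    other_q_high = q_high[called],
    gap = ifelse(under[called],
                 q_low[called] - delta - target_mean[called],
                 target_mean[called] - q_high[called] - delta),
    uniqueness = other_median[called] - target_mean[called],
    n_values = n_values[called],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "params") <- list(target_tissue = target_tissue, delta = delta,
                              q = q, min_values = min_values,
                              per_tissue_quantiles = per_tissue_quantiles,
                              quantile_type = 7L,
                              n_probes_tested = nrow(m))
  out
}

#' Uniqueness distance of a tissue-unique site
#'
#' The signed distance between the pooled non-target median and the target
#' tissue mean: `median(other samples) - mean(target samples)`. Positive
#' for sites under-methylated in the target tissue, negative for
#' over-methylated sites; its magnitude measures how far the site's
#' methylation stands out from the rest of the body.
#'
#' @param calls Data frame from [call_unique_sites()] (the `uniqueness`
#'   column is recomputed from the atlas).
#' @param atlas The [tissue_atlas()] the calls came from.
#' @return Named numeric vector of signed distances, one per call.
#' @export
uniqueness_score <- function(calls, atlas) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  params <- attr(calls, "params")
  target <- if (!is.null(params)) params$target_tissue else
    stop("calls carry no target-tissue metadata")
  is_target <- atlas$tissues == target
  m <- atlas$matrix[calls$probe_id, , drop = FALSE]
  target_mean <- rowMeans(m[, is_target, drop = FALSE], na.rm = TRUE)
  other_median <- apply(m[, !is_target, drop = FALSE], 1L,
                        stats::median, na.rm = TRUE)
  stats::setNames(other_median - target_mean, calls$probe_id)
}

#' Count unique-site calls by direction
#'
#' @param calls Data frame from [call_unique_sites()].
#' @return Named integer vector `c(n_under, n_over)`.
#' @export
classify_directions <- function(calls) {
  c(n_under = sum(calls$direction == "under"),
    n_over  = sum(calls$direction == "over"))
}
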