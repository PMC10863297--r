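# Per-sample epigenetic information-loss score: the number of
# tissue-unique sites whose methylation in a sample has moved from the
# healthy-tissue median toward the cross-tissue common baseline by at
# least k reference standard deviations.

#' Build per-probe reference statistics for the information-loss score
#'
#' For each called unique site, computes the median and (n-1) standard
#' deviation of beta values over a reference set of samples, and the
#' direction from that median toward the cross-tissue common baseline.
#' Probes with zero reference SD (no spread to calibrate against) are
#' excluded with a message, as are probes where the baseline coincides
#' with the reference median.
#'
#' @param matrix Probes x samples beta matrix of the reference population.
#' @param sheet Sample sheet aligned to `matrix`.
#' @param calls Data frame from [call_unique_sites()]; provides the probes
#'   and the common baseline (`target_mean + uniqueness`).
#' @param reference_rule Logical vector over `sheet` rows, or a predicate
#'   function of the sheet, selecting the reference samples. Default:
#'   the healthy stratum `IF < 20`.
#' @return A data frame with columns `probe_id`, `ref_median`, `ref_sd`,
#'   `baseline`, `baseline_direction` (+1 when the common baseline lies
#'   above the reference median, -1 below).
#' @export
build_reference <- function(matrix, sheet, calls,
                            reference_rule = function(s) !is.na(s$IF) &
                              s$IF < 20) {
  al <- align_samples(matrix, sheet)
  sel <- if (is.function(reference_rule)) reference_rule(al$sheet) else
    reference_rule
  sel[is.na(sel)] <- FALSE
  if (sum(sel) < 3L) {
    stop("reference rule selects ", sum(sel), " samples; need >= 3")
  }
  probes <- intersect(calls$probe_id, rownames(al$matrix))
  if (length(probes) == 0L) stop("no called probe present in the matrix")
  m <- al$matrix[probes, sel, drop = FALSE]
  ref_median <- apply(m, 1L, stats::median, na.rm = TRUE)
  ref_sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  baseline <- calls$target_mean + calls$uniqueness
  baseline <- baseline[match(probes, calls$probe_id)]
  dir <- sign(baseline - ref_median)
  drop <- is.na(ref_sd) | ref_sd == 0 | dir == 0
  if (any(drop)) {
    message("build_reference: excluded ", sum(drop),
            " probe(s) with zero reference SD or zero baseline offset")
  }
  out <- data.frame(
    probe_id = probes[!drop],
    ref_median = ref_median[!drop],
    ref_sd = ref_sd[!drop],
    baseline = baseline[!drop],
    baseline_direction = dir[!drop],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_reference_samples") <- sum(sel)
  out
}

#' Information-loss score of one sample
#'
#' Counts the reference sites at which the sample's beta value deviates
#' from the reference median toward the common baseline by at least
#' `k` reference standard deviations:
#' `(value - ref_median) * baseline_direction >= k * ref_sd`.
#' Deviations away from the baseline never count, whatever their size.
#' Missing values drop the site from the eligible set.
#'
#' @param sample_betas Named numeric vector of beta values (names = probe
#'   ids), or an unnamed vector aligned to `reference$probe_id`.
#' @param reference Data frame from [build_reference()].
#' @param k SD multiplier (> 0, default 2).
#' @return A list with `score` (count of drifted sites), `n_eligible`
#'   (sites with a non-missing value) and `fraction` (score / n_eligible).
#' @export
information_loss_score <- function(sample_betas, reference, k = 2) {
  stopifnot(k > 0)
  if (!is.null(names(sample_betas))) {
    v <- sample_betas[reference$probe_id]
  } else {
    stopifnot(length(sample_betas) == nrow(reference))
    v <- sample_betas
  }
  eligible <- !is.na(v)
  if (!any(eligible)) {
    stop("sample shares no non-missing probe with the reference")
  }
  drifted <- eligible &
    (v - reference$ref_median) * reference$baseline_direction >=
      k * reference$ref_sd
  score <- sum(drifted)
  n_eligible <- sum(eligible)
  list(score = score, n_eligible = n_eligible,
       fraction = score / n_eligible)
}

#' Score a cohort and correlate the score with kidney phenotypes
#'
#' Computes the information-loss score for every sample of a cohort and
#' its Pearson correlation with interstitial fibrosis (IF) and eGFR.
#'
#' @param matrix Probes x samples cohort beta matrix.
#' @param sheet Sample sheet with `IF` and/or `eGFR`.
#' @param reference Data frame from [build_reference()].
#' @param k SD multiplier (default 2).
#' @return A list with `scores` (data frame: `sample_id`, `score`,
#'   `n_eligible`, `fraction`) and `correlations` (data frame:
#'   `phenotype`, `r`, `p`, `n`; `NA` where the phenotype is absent or
#'   the scores are constant).
#' @export
score_cohort <- function(matrix, sheet, reference, k = 2) {
  al <- align_samples(matrix, sheet)
  if (nrow(al$sheet) < 3L) stop("need >= 3 samples to score a cohort")
  m <- al$matrix
  res <- lapply(colnames(m), function(s) {
    information_loss_score(stats::setNames(m[, s], rownames(m)),
                           reference, k = k)
  })
  scores <- data.frame(
    sample_id = colnames(m),
    score = vapply(res, `[[`, numeric(1), "score"),
    n_eligible = vapply(res, `[[`, numeric(1), "n_eligible"),
    fraction = vapply(res, `[[`, numeric(1), "fraction"),
    stringsAsFactors = FALSE
  )
  cor_one <- function(pheno) {
    y <- al$sheet[[pheno]]
    ok <- !is.na(y)
    if (sum(ok) < 3L || stats::sd(scores$score[ok]) == 0 ||
        stats::sd(y[ok]) == 0) {
      return(data.frame(phenotype = pheno, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    r <- stats::cor(scores$score[ok], y[ok])
    tp <- t_and_p(r, sum(ok))
    data.frame(phenotype = pheno, r = r, p = tp$p, n = sum(ok))
  }
  correlations <- do.call(rbind, lapply(intersect(c("IF", "eGFR"),
                                                  colnames(al$sheet)),
                                        cor_one))
  rownames(correlations) <- NULL
  list(scores = scores, correlations = correlations)
}
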