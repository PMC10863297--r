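# Per-CpG association of beta values with a continuous phenotype:
# Pearson r, the t statistic t = r * sqrt(n-2) / sqrt(1-r^2), two-sided
# p-values from the t distribution with n-2 df, and Bonferroni control.

#' t statistic and two-sided p-value for a Pearson correlation
#'
#' Computes `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and its two-sided tail
#' probability under the Student t distribution with `n - 2` degrees of
#' freedom. A perfect correlation (`|r| = 1`) has no finite t; it is
#' returned as `t = Inf` (signed), `p = 0`, with `exact_fit = TRUE`.
#'
#' @param r Pearson correlation coefficient(s) in \[-1, 1\].
#' @param n Number of paired observations (>= 3), recycled against `r`.
#' @return A data frame with columns `t`, `p` and `exact_fit`.
#' @examples
#' t_and_p(-0.74, 85)   # p well below 1e-13
#' t_and_p(0, 10)       # t = 0, p = 1
#' @export
t_and_p <- function(r, n) {
  if (any(n < 3)) stop("n must be >= 3 for a correlation t test")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  exact <- abs(r) == 1
  t <- ifelse(exact, sign(r) * Inf, r * sqrt(n - 2) / sqrt(1 - r^2))
  p <- ifelse(exact, 0, 2 * stats::pt(-abs(t), df = n - 2))
  data.frame(t = t, p = p, exact_fit = exact)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for `m` tests.
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, m * p)
}

#' Per-probe Pearson correlation scan against a phenotype
#'
#' For every probe, computes the Pearson correlation between its beta
#' values and a continuous phenotype over pairwise-complete observations
#' (each probe uses every sample where both its beta value and the
#' phenotype are present). Probes with fewer than `min_pairs` complete
#' pairs, or with zero variance over the used samples, are omitted; the
#' Bonferroni multiplier `m` is the number of probes actually tested.
#'
#' @param matrix Probes x samples beta matrix (missing entries `NA`).
#' @param phenotype Numeric vector of per-sample phenotype values, either
#'   named by sample id or in matrix column order. Samples with missing
#'   phenotype are dropped.
#' @param min_pairs Minimum complete pairs per probe (default 10).
#' @return A data frame with one row per tested probe: `probe_id`, `r`,
#'   `t`, `p`, `p_bonferroni`, `n_used`, `sign` (`"positive"`,
#'   `"negative"` or `"zero"`) and `exact_fit`. The attribute `"omitted"`
#'   holds a named count of probes skipped, by reason.
#' @examples
#' m <- matrix(runif(40), 4, 10,
#'             dimnames = list(paste0("cg", 1:4), paste0("s", 1:10)))
#' pearson_scan(m, rnorm(10), min_pairs = 5)
#' @export
pearson_scan <- function(matrix, phenotype, min_pairs = 10) {
  stopifnot(is.matrix(matrix), min_pairs >= 3)
  if (!is.null(names(phenotype))) {
    phenotype <- phenotype[colnames(matrix)]
  }
  if (length(phenotype) != ncol(matrix)) {
    stop("phenotype length does not match the number of samples")
  }
  use <- !is.na(phenotype)
  x <- matrix[, use, drop = FALSE]
  y <- as.numeric(phenotype[use])
  if (length(y) < min_pairs) {
    stop("fewer than min_pairs = ", min_pairs,
         " samples with phenotype values")
  }
  if (stats::var(y) == 0) {
    stop("phenotype is constant across the usable samples")
  }

  # Pairwise-complete moments, vectorized over probes: with obs = 1 where
  # the beta value is present, accumulate per-probe sums of x, x^2, y, y^2
  # and xy restricted to complete pairs.
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  n_used <- as.integer(obs %*% rep(1, length(y)))
  sy  <- as.numeric(obs %*% y)
  syy <- as.numeric(obs %*% y^2)
  sx  <- rowSums(x0)
  sxx <- rowSums(x0^2)
  sxy <- as.numeric(x0 %*% y)

  vx <- n_used * sxx - sx^2
  vy <- n_used * syy - sy^2
  r <- suppressWarnings((n_used * sxy - sx * sy) / sqrt(vx * vy))
  r <- pmin(pmax(r, -1), 1)

  few  <- n_used < min_pairs
  flat <- !few & (vx <= 0 | vy <= 0)
  keep <- !few & !flat
  omitted <- c(too_few_pairs = sum(few), zero_variance = sum(flat))
  if (any(!keep)) {
    message("pearson_scan: omitted ", sum(!keep), " probe(s) (",
            omitted[["too_few_pairs"]], " with < ", min_pairs,
            " pairs, ", omitted[["zero_variance"]], " with zero variance)")
  }
  if (!any(keep)) stop("no probe passed the min_pairs/variance filters")

  r <- r[keep]
  n_used <- n_used[keep]
  tp <- t_and_p(r, n_used)
  m <- sum(keep)
  out <- data.frame(
    probe_id = rownames(matrix)[keep],
    r = r,
    t = tp$t,
    p = tp$p,
    p_bonferroni = bonferroni(tp$p, m),
    n_used = n_used,
    sign = ifelse(r > 0, "positive", ifelse(r < 0, "negative", "zero")),
    exact_fit = tp$exact_fit,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  attr(out, "m_tests") <- m
  out
}

#' Partial correlation with one or more covariates
#'
#' Correlation between `x` and `y` after removing the linear contribution
#' of the covariates, computed as the Pearson correlation of the residuals
#' of `x ~ covariates` and `y ~ covariates` (equivalent to the recursive
#' first-order formula). Complete-case analysis.
#'
#' @param x,y Numeric vectors.
#' @param covariates A numeric vector, matrix or data frame of covariates,
#'   aligned with `x` and `y`.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  storage.mode(z) <- "double"
  stopifnot(length(x) == length(y), nrow(z) == length(x))
  cc <- stats::complete.cases(x, y, z)
  if (sum(cc) < ncol(z) + 3) {
    stop("need at least ", ncol(z) + 3, " complete cases, have ", sum(cc))
  }
  x <- x[cc]; y <- y[cc]; z <- z[cc, , drop = FALSE]
  q <- qr(cbind(1, z))
  if (q$rank < ncol(z) + 1) stop("singular covariate set")
  rx <- qr.resid(q, x)
  ry <- qr.resid(q, y)
  # fully explained variables leave only round-off in the residuals
  if (stats::sd(rx) <= 1e-10 * stats::sd(x) ||
      stats::sd(ry) <= 1e-10 * stats::sd(y)) {
    return(0)
  }
  stats::cor(rx, ry)
}

#' Sign split of selected correlation records
#'
#' Fractions of positively and negatively correlated probes among a
#' selection, e.g. the probes passing Bonferroni correction. Records with
#' exactly zero correlation are excluded (and reported via a message), so
#' the two fractions sum to 1.
#'
#' @param records Data frame from [pearson_scan()].
#' @param selection Logical vector, row indices, or a predicate function
#'   applied to `records` (default: `p_bonferroni < 0.05`).
#' @return Named numeric vector `c(fraction_positive, fraction_negative)`.
#' @export
sign_split <- function(records, selection = NULL) {
  if (is.null(selection)) {
    selection <- records$p_bonferroni < 0.05
  } else if (is.function(selection)) {
    selection <- selection(records)
  }
  sel <- records[selection, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty selection in sign_split")
  zero <- sel$r == 0
  if (any(zero)) {
    message("sign_split: excluded ", sum(zero), " record(s) with r = 0")
    sel <- sel[!zero, , drop = FALSE]
    if (nrow(sel) == 0L) stop("all selected records have r = 0")
  }
  pos <- mean(sel$r > 0)
  c(fraction_positive = pos, fraction_negative = 1 - pos)
}

#' Top fraction of probes by correlation strength
#'
#' Selects the `ceiling(fraction * N)` probes with the largest ranking key
#' (absolute or signed correlation), with a deterministic lexicographic
#' tie-break on probe id.
#'
#' @param records Data frame from [pearson_scan()].
#' @param fraction Fraction in (0, 1\].
#' @param by Ranking key: `"abs_r"` (default) or `"r"`.
#' @return Character vector of selected probe ids.
#' @export
top_fraction <- function(records, fraction = 0.10, by = c("abs_r", "r")) {
  by <- match.arg(by)
  stopifnot(fraction > 0, fraction <= 1)
  key <- if (by == "abs_r") abs(records$r) else records$r
  k <- ceiling(fraction * nrow(records))
  ord <- order(-key, records$probe_id)
  records$probe_id[ord[seq_len(k)]]
}
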