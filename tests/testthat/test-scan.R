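test_that("t_and_p reproduces the correlation t distribution", {
  z <- t_and_p(0, 10)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)

  # cross-check against cor.test on data constructed to a known r
  set.seed(7)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  r <- cor(x, y)
  ref <- cor.test(x, y)
  z <- t_and_p(r, 20)
  expect_equal(z$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(z$p, ref$p.value, tolerance = 1e-10)

  # antisymmetry and monotonicity
  expect_equal(t_and_p(-0.4, 30)$t, -t_and_p(0.4, 30)$t)
  expect_equal(t_and_p(-0.4, 30)$p, t_and_p(0.4, 30)$p)
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(t_and_p(rs, 30)$p) < 0))
  expect_true(t_and_p(0.4, 50)$p < t_and_p(0.4, 20)$p)

  # exact fits flagged, not silently propagated
  z1 <- t_and_p(1, 10)
  expect_true(z1$exact_fit)
  expect_equal(z1$p, 0)
  expect_error(t_and_p(0.5, 2), "n must be >= 3")
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(c(0, 1e-3), 100), c(0, 0.1))
})

test_that("pearson_scan matches a naive pairwise-complete loop", {
  g <- generate_atlas(small_config())
  co <- generate_kidney_cohort(g$truth, 40, small_config())
  m <- co$matrix[1:200, ]
  pheno <- setNames(co$sheet$IF, co$sheet$sample_id)
  scan <- suppressMessages(pearson_scan(m, pheno, min_pairs = 10))

  naive <- lapply(rownames(m), function(pid) {
    x <- m[pid, ]
    ok <- !is.na(x) & !is.na(pheno)
    if (sum(ok) < 10 || sd(x[ok]) == 0) return(NULL)
    ct <- cor.test(x[ok], pheno[ok])
    data.frame(probe_id = pid, r = unname(ct$estimate),
               t = unname(ct$statistic), p = ct$p.value, n = sum(ok))
  })
  naive <- do.call(rbind, naive)
  expect_identical(scan$probe_id, naive$probe_id)
  expect_equal(scan$r, naive$r, tolerance = 1e-12)
  expect_equal(scan$t, naive$t, tolerance = 1e-10)
  expect_equal(scan$p, naive$p, tolerance = 1e-12)
  expect_identical(scan$n_used, naive$n)
  expect_equal(scan$p_bonferroni, pmin(1, nrow(naive) * scan$p))
})

test_that("pearson_scan handles perfect fits, filters, and errors", {
  pheno <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  m <- rbind(cg_perfect = pheno, cg_flat = rep(0.5, 10),
             cg_noise = runif(10))
  colnames(m) <- sprintf("s%02d", 1:10)
  scan <- suppressMessages(pearson_scan(m, pheno, min_pairs = 5))
  expect_false("cg_flat" %in% scan$probe_id)  # zero variance omitted
  perfect <- scan[scan$probe_id == "cg_perfect", ]
  expect_equal(perfect$r, 1)
  expect_true(perfect$exact_fit)
  expect_equal(perfect$p, 0)

  expect_error(pearson_scan(m, rep(1, 10), min_pairs = 5), "constant")
  expect_error(pearson_scan(m, pheno, min_pairs = 20), "fewer than")
})

test_that("matrix is filled by probe not by sample", {
  # guard against orientation mix-ups in the vectorized scan
  m <- tiny_matrix(runif(50), 5, 10)
  pheno <- m[3, ] + rnorm(10, sd = 1e-8)
  scan <- pearson_scan(m, pheno, min_pairs = 5)
  best <- scan$probe_id[which.max(abs(scan$r))]
  expect_identical(best, rownames(m)[3])
})

test_that("partial_correlation equals residual-on-residual regression", {
  set.seed(11)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.5 * z1 - 0.3 * z2 + rnorm(n)
  y <- -0.2 * z1 + 0.4 * z2 + 0.3 * x + rnorm(n)
  z <- cbind(z1, z2)
  rp <- partial_correlation(x, y, z)
  oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  expect_equal(rp, oracle, tolerance = 1e-10)

  # first-order recursion formula for a single covariate
  r1 <- partial_correlation(x, y, z1)
  rxy <- cor(x, y); rxz <- cor(x, z1); ryz <- cor(y, z1)
  expect_equal(r1, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)

  # x fully explained by the covariate
  expect_equal(partial_correlation(z1, y, z1), 0)
  expect_error(partial_correlation(x, y, cbind(z1, z1)), "singular")
})

test_that("partial correlation with an irrelevant covariate is near plain r", {
  set.seed(13)
  n <- 10000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  expect_lt(abs(partial_correlation(x, y, z) - cor(x, y)), 0.05)
})

test_that("sign_split partitions selected records, excluding r = 0", {
  rec <- data.frame(probe_id = paste0("cg", 1:6),
                    r = c(0.5, 0.2, -0.1, -0.3, 0, 0.4),
                    p_bonferroni = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.9),
                    stringsAsFactors = FALSE)
  expect_message(s <- sign_split(rec, rec$p_bonferroni < 0.05), "r = 0")
  expect_equal(unname(s), c(0.5, 0.5))
  expect_equal(sum(s), 1)
  expect_equal(unname(sign_split(rec, rec$r > 0)),
               c(1, 0))
  expect_error(sign_split(rec, rep(FALSE, 6)), "empty selection")
})

test_that("top_fraction matches a full sort with probe_id tie-break", {
  set.seed(3)
  rec <- data.frame(probe_id = sprintf("cg%03d", sample(100)),
                    r = round(rnorm(100), 2), stringsAsFactors = FALSE)
  top <- top_fraction(rec, 0.10)
  ord <- rec[order(-abs(rec$r), rec$probe_id), ]
  expect_identical(top, ord$probe_id[1:10])
  expect_identical(sort(top_fraction(rec, 1)), sort(rec$probe_id))
  # signed ranking picks the most positive r
  expect_identical(top_fraction(rec, 0.01, by = "r"),
                   rec$probe_id[which.max(rec$r)])
  ties <- data.frame(probe_id = c("cgB", "cgA", "cgC"),
                     r = c(0.5, 0.5, 0.1), stringsAsFactors = FALSE)
  expect_identical(top_fraction(ties, 1 / 3), "cgA")
})
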