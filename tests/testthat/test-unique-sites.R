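make_atlas <- function(m, n_kidney, n_other) {
  tissue_atlas(m, rep(c("kidney", "liver", "lung"),
                      c(n_kidney, ceiling(n_other / 2),
                        floor(n_other / 2))))
}

test_that("a constant matrix yields zero calls", {
  m <- tiny_matrix(rep(0.5, 10 * 12), 10, 12)
  calls <- call_unique_sites(make_atlas(m, 4, 8), "kidney",
                             min_values = 1)
  expect_identical(nrow(calls), 0L)
  expect_identical(unname(classify_directions(calls)), c(0L, 0L))
})

test_that("the quantile-offset rule calls a constructed under probe", {
  # kidney mean 0.35; all other samples >= 0.9 -> 5% quantile >= 0.9,
  # so the under margin is at least 0.9 - 0.2 - 0.35 = 0.35
  m <- tiny_matrix(0.5, 2, 12)
  m[1, ] <- c(rep(0.35, 4), rep(c(0.90, 0.95), 4))
  calls <- call_unique_sites(make_atlas(m, 4, 8), "kidney",
                             min_values = 1)
  expect_identical(calls$probe_id, "cg001")
  expect_identical(calls$direction, "under")
  expect_equal(calls$target_mean, 0.35)
  expect_gte(calls$gap, 0.35)
  expect_equal(calls$uniqueness, median(rep(c(0.90, 0.95), 4)) - 0.35)
})

test_that("uniqueness_score is the signed other-median minus target mean", {
  m <- tiny_matrix(0.5, 2, 12)
  m[1, ] <- c(rep(0.35, 4), rep(0.95, 8))     # under: +0.60
  m[2, ] <- c(rep(0.80, 4), rep(0.10, 8))     # over:  -0.70
  calls <- call_unique_sites(make_atlas(m, 4, 8), "kidney",
                             min_values = 1)
  u <- uniqueness_score(calls, make_atlas(m, 4, 8))
  expect_equal(unname(u["cg001"]), 0.60)
  expect_equal(unname(u["cg002"]), -0.70)
  expect_equal(calls$uniqueness, unname(u[calls$probe_id]))
  expect_lt(calls$uniqueness[calls$direction == "over"], 0)
})

test_that("planted unique sites are recovered with both directions", {
  cfg <- small_config()
  g <- generate_atlas(cfg)
  calls <- call_unique_sites(g$atlas, "kidney")
  truth_under <- planted_ids(g$truth, "unique_under")
  truth_over <- planted_ids(g$truth, "unique_over")
  expect_gte(mean(truth_under %in%
                    calls$probe_id[calls$direction == "under"]), 0.9)
  expect_gte(mean(truth_over %in%
                    calls$probe_id[calls$direction == "over"]), 0.9)
  # precision: nothing but planted sites is called
  expect_true(all(calls$probe_id %in% c(truth_under, truth_over)))
  dirs <- classify_directions(calls)
  expect_identical(sum(dirs), nrow(calls))
})

test_that("complement symmetry swaps under and over calls exactly", {
  cfg <- small_config()
  g <- generate_atlas(cfg)
  calls <- call_unique_sites(g$atlas, "kidney")
  flipped <- tissue_atlas(1 - g$atlas$matrix, g$atlas$tissues)
  calls_f <- call_unique_sites(flipped, "kidney")
  expect_identical(sort(calls$probe_id[calls$direction == "under"]),
                   sort(calls_f$probe_id[calls_f$direction == "over"]))
  expect_identical(sort(calls$probe_id[calls$direction == "over"]),
                   sort(calls_f$probe_id[calls_f$direction == "under"]))
})

test_that("raising delta or narrowing the tail never adds calls", {
  g <- generate_atlas(small_config())
  n02 <- nrow(call_unique_sites(g$atlas, "kidney", delta = 0.2))
  n03 <- nrow(call_unique_sites(g$atlas, "kidney", delta = 0.3))
  n05 <- nrow(call_unique_sites(g$atlas, "kidney", delta = 0.5))
  expect_true(n02 >= n03 && n03 >= n05)
  u_wide <- call_unique_sites(g$atlas, "kidney", q = 0.10)
  u_narrow <- call_unique_sites(g$atlas, "kidney", q = 0.01)
  n_under <- function(x) sum(x$direction == "under")
  expect_lte(n_under(u_narrow), n_under(u_wide))
})

test_that("calls are invariant to sample order and non-target labels", {
  g <- generate_atlas(small_config())
  calls <- call_unique_sites(g$atlas, "kidney")
  perm <- sample(ncol(g$atlas$matrix))
  shuffled <- tissue_atlas(g$atlas$matrix[, perm],
                           g$atlas$tissues[perm])
  calls_p <- call_unique_sites(shuffled, "kidney")
  expect_equal(calls[order(calls$probe_id), ],
               calls_p[order(calls_p$probe_id), ],
               ignore_attr = TRUE)

  relabeled <- g$atlas$tissues
  relabeled[relabeled == "tissue1"] <- "tissueX"
  calls_r <- call_unique_sites(tissue_atlas(g$atlas$matrix, relabeled),
                               "kidney")
  expect_identical(sort(calls$probe_id), sort(calls_r$probe_id))
})

test_that("min_values filter and argument validation behave", {
  m <- tiny_matrix(0.5, 2, 12)
  m[1, ] <- c(rep(0.3, 4), rep(0.95, 8))
  m[1, 5:10] <- NA  # only 6 values left on the callable probe
  at <- make_atlas(m, 4, 8)
  expect_identical(nrow(call_unique_sites(at, "kidney", min_values = 7)),
                   0L)
  expect_identical(nrow(call_unique_sites(at, "kidney", min_values = 5)),
                   1L)
  expect_error(call_unique_sites(at, "brain"), "not present")
  expect_error(call_unique_sites(at, "kidney", delta = -0.1),
               "non-negative")
  expect_error(call_unique_sites(at, "kidney", q = 0.6), "\\(0, 0.5\\)")
})

test_that("no probe is called in both directions", {
  g <- generate_atlas(small_config())
  for (d in c(0.05, 0.2)) {
    calls <- call_unique_sites(g$atlas, "kidney", delta = d)
    expect_identical(anyDuplicated(calls$probe_id), 0L)
  }
})
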