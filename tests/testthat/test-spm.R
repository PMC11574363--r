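test_that("the paired t-field matches the scalar paired t-test per node", {
  set.seed(11)
  a <- matrix(rnorm(12 * 101), 12, 101)
  b <- matrix(rnorm(12 * 101), 12, 101)
  rownames(a) <- rownames(b) <- sprintf("P%02d", 1:12)
  res <- spm_paired_t(a, b)
  expect_equal(res$df, 11)
  for (q in c(1, 37, 101)) {
    oracle <- t.test(a[, q], b[, q], paired = TRUE)$statistic
    expect_equal(res$t_field[q], unname(oracle), tolerance = 1e-10)
  }
  # identical conditions -> zero field
  z <- spm_paired_t(a, a)
  expect_true(all(is.na(z$t_field)))      # sd = 0 at every node: flagged
  expect_length(z$flagged_nodes, 101)
  res2 <- spm_paired_t(a, a + matrix(rnorm(12 * 101), 12, 101))
  expect_false(any(is.na(res2$t_field)))
  # participant sets must match
  b2 <- b; rownames(b2)[1] <- "P99"
  expect_error(spm_paired_t(a, b2), "pairing error")
})

test_that("FWHM estimation matches analytic and calibrated values", {
  set.seed(12)
  # white noise: gradient variance 2 -> fwhm = sqrt(4 ln 2 / 2)
  f <- replicate(100, estimate_fwhm(matrix(rnorm(21 * 101), 21, 101)))
  expect_equal(mean(f), sqrt(4 * log(2) / 2), tolerance = 0.02)
  # smoothed with FWHM 20 -> mean estimate within [17, 23]
  est <- replicate(200, estimate_fwhm(smooth_gaussian_fields(21, 101, 20)))
  expect_gt(mean(est), 17); expect_lt(mean(est), 23)
  # perfectly smooth residuals (common spatial profile): huge fwhm
  lin <- outer(rnorm(40), seq(1, 2, length.out = 101))
  expect_gte(estimate_fwhm(lin), 101)
})

test_that("the RFT threshold has the right limits and monotonicity", {
  # zero-resel limit: the scalar two-sided t quantile
  expect_equal(rft_threshold(20, 1e8, alpha = 0.05), qt(0.975, 20),
               tolerance = 0.01)
  expect_equal(rft_threshold(20, 1e8, alpha = 0.05, two_sided = FALSE),
               qt(0.95, 20), tolerance = 0.01)
  # more resels -> larger threshold
  expect_gt(rft_threshold(20, 5), rft_threshold(20, 15))
  expect_gt(rft_threshold(20, 15), rft_threshold(20, 60))
  expect_error(rft_threshold(1, 10), "df")
  expect_error(rft_threshold(20, 10, alpha = 0), "alpha")
})

test_that("RFT and sign-flip permutation thresholds agree on smooth nulls", {
  set.seed(13)
  rel <- replicate(5, {
    d <- smooth_gaussian_fields(21, 101, 15)
    fw <- estimate_fwhm(sweep(d, 2, colMeans(d)))
    a <- rft_threshold(20, fw, alpha = 0.05)
    b <- permutation_threshold(d, alpha = 0.05, n_perm = 5000, seed = 99)
    abs(a - b) / b
  })
  expect_lt(median(rel), 0.05)
})

test_that("permutation threshold edge cases behave as specified", {
  set.seed(14)
  d <- smooth_gaussian_fields(5, 101, 12)
  # n = 5: exhaustive 32 sign patterns, identical across seeds
  t1 <- permutation_threshold(d, alpha = 0.05, n_perm = 10000, seed = 1)
  t2 <- permutation_threshold(d, alpha = 0.05, n_perm = 10000, seed = 2)
  expect_identical(t1, t2)
  # alpha = 1 -> minimum of the max-t distribution (quantile type 1)
  d2 <- smooth_gaussian_fields(8, 101, 12)
  tmin <- permutation_threshold(d2, alpha = 1 - 1e-12, n_perm = 256,
                                seed = 3)
  tmax <- permutation_threshold(d2, alpha = 1e-12, n_perm = 256, seed = 3)
  expect_lt(tmin, tmax)
  expect_error(permutation_threshold(d2[1:3, ]), "at least 5")
})

test_that("clusters are the maximal suprathreshold runs", {
  tf <- rep(0, 101)
  tf[21:41] <- 5
  tf[60] <- -6
  cl <- spm_clusters(tf, 3)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start_pct, c(20, 59))
  expect_equal(cl$end_pct, c(40, 59))
  expect_equal(cl$sign, c(1, -1))
  expect_equal(spm_clusters(rep(0, 101), 3) |> nrow(), 0)
})

test_that("spm_compare assembles a coherent result with Bonferroni alpha", {
  set.seed(15)
  a <- smooth_gaussian_fields(10, 101, 15)
  b <- smooth_gaussian_fields(10, 101, 15)
  b[, 30:50] <- b[, 30:50] + 3
  rownames(a) <- rownames(b) <- sprintf("P%02d", 1:10)
  res <- spm_compare(a, b, alpha = 0.05, bonferroni_m = 6,
                     comparison = "test")
  expect_s3_class(res, "sandgait_spm")
  expect_equal(res$alpha_effective, 0.05 / 6)
  expect_true(nrow(res$clusters) >= 1)
  expect_true(any(res$clusters$start_pct <= 50 &
                    res$clusters$end_pct >= 30))
  td <- tidy(res)
  expect_equal(nrow(td), 101)
  expect_true(any(td$significant))
  gl <- glance(res)
  expect_equal(gl$n_clusters, nrow(res$clusters))
})
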