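test_that("one-way ANOVA matches a hand sums-of-squares oracle", {
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 5),
    y = c(6, 8, 4, 5, 3, 8, 12, 9, 11, 8, 13, 9, 11, 8, 12))
  res <- anova_tukey(d, "y", "g")
  # hand oracle: SS decomposition
  gm <- mean(d$y)
  means <- tapply(d$y, d$g, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((d$y - means[d$g])^2)
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 12)
  expect_equal(res$p, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("separated groups are significant; identical values give F = 0", {
  set.seed(21)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 6),
                      y = c(rnorm(6, 0, 1e-6), rnorm(6, 10, 1e-6)))
  res <- anova_tukey(d, "y", "g")
  expect_lt(res$p, 1e-12)
  expect_true(all(tidy(res)$p_adj < 1e-6))
  same <- anova_tukey(tibble::tibble(g = rep(c("a", "b"), each = 3),
                                     y = rep(4, 6)), "y", "g")
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  # one zero-variance group among variable groups: still finite
  mix <- anova_tukey(tibble::tibble(
    g = rep(c("a", "b"), each = 4),
    y = c(rep(1, 4), c(4, 5, 6, 7))), "y", "g")
  expect_true(is.finite(mix$f))
})

test_that("the ANOVA keeps its nominal type-I rate under the null", {
  set.seed(22)
  rej <- replicate(600, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 8),
                        y = rnorm(24))
    anova_tukey(d, "y", "g")$p < 0.05
  })
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.085)
})

test_that("Spearman correlations are exact for monotone pairs", {
  set.seed(23)
  x <- rnorm(30)
  d <- tibble::tibble(x = x, expx = exp(x), negx = -x, z = rnorm(30))
  res <- spearman_correlogram(d, c("x", "expx", "negx", "z"))
  expect_equal(res$rho["x", "expx"], 1)
  expect_equal(res$rho["x", "negx"], -1)
  expect_equal(res$rho, t(res$rho))
  expect_true(all(abs(res$rho) <= 1 + 1e-12, na.rm = TRUE))
  # p-values via the t approximation
  r <- res$rho["x", "z"]
  tstat <- r * sqrt((30 - 2) / (1 - r^2))
  expect_equal(res$p["x", "z"], 2 * pt(abs(tstat), 28, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("first-PC ordering matches an independent eigen oracle", {
  set.seed(24)
  for (i in 1:5) {
    n <- 40
    base <- rnorm(n)
    d <- tibble::tibble(
      v1 = base + rnorm(n, 0, 0.1),
      v2 = base + rnorm(n, 0, 0.1),
      v3 = rnorm(n),
      v4 = -base + rnorm(n, 0, 0.5))
    res <- spearman_correlogram(d, c("v1", "v2", "v3", "v4"))
    ev <- power_iter_ev(res$rho)
    oracle_order <- colnames(res$rho)[order(-ev)]
    expect_equal(res$order, oracle_order)
    # the identical pair sits adjacent
    pos <- match(c("v1", "v2"), res$order)
    expect_equal(abs(diff(pos)), 1)
  }
})

test_that("constant variables are flagged, not fatal", {
  d <- tibble::tibble(a = rnorm(10), b = rnorm(10), c = rep(1, 10))
  res <- spearman_correlogram(d, c("a", "b", "c"))
  expect_equal(res$flagged, "c")
  expect_true(all(is.na(res$rho["c", ])))
  expect_false(is.na(res$rho["a", "b"]))
})

test_that("the mixed model recovers simulated fixed and random effects", {
  set.seed(25)
  n_p <- 21
  d <- expand.grid(participant_id = sprintf("P%02d", 1:n_p),
                   substrate_id = c("floor", "sand"),
                   trial = 1:3, stringsAsFactors = FALSE)
  b_p <- rnorm(n_p, 0, 0.1)
  names(b_p) <- sprintf("P%02d", 1:n_p)
  d$speed <- 1.25 - 0.15 * (d$substrate_id == "sand") +
    b_p[d$participant_id] + rnorm(nrow(d), 0, 0.05)
  fit <- fit_lmm(d, "speed", fixed = "substrate_id")
  beta <- fit$fixed[fit$fixed$term == "substrate_idsand", ]
  expect_lt(abs(beta$estimate + 0.15), 3 * beta$se)
  expect_lt(abs(sqrt(fit$varcomp$variance[1]) - 0.1), 0.05)
  expect_lt(abs(sqrt(fit$varcomp$variance[2]) - 0.05), 0.01)
  expect_false(fit$singular)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("no participant heterogeneity yields a ~zero variance component", {
  set.seed(26)
  d <- expand.grid(participant_id = sprintf("P%02d", 1:10),
                   substrate_id = c("floor", "sand"), trial = 1:4,
                   stringsAsFactors = FALSE)
  d$speed <- 1.2 + rnorm(nrow(d), 0, 0.05)
  fit <- fit_lmm(d, "speed", fixed = "substrate_id")
  expect_lt(fit$varcomp$variance[1], 1e-4)
  expect_error(fit_lmm(dplyr::mutate(d, speed = 1), "speed"),
               "constant")
})
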