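#' Node-wise paired t-field over 101-node curves
#'
#' Paired t-statistic at every gait-cycle node between two conditions
#' measured on the same participants (one 101-node mean curve per
#' participant per condition; strides must be averaged within participant
#' first). At node q, with differences `d_i(q) = a_i(q) - b_i(q)`:
#' `t(q) = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`. Nodes with zero
#' difference variance yield `NA` and are flagged.
#'
#' @param curves_a,curves_b Numeric matrices, participants x 101 nodes, with
#'   matching row names (participant ids) or matching row order.
#' @return List: `t_field` (length-101), `df`, `diffs` (n x 101 matrix),
#'   `flagged_nodes` (indices with zero variance).
#' @export
spm_paired_t <- function(curves_a, curves_b) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  assert_that(nrow(curves_a) >= 3, "need at least 3 participants")
  assert_that(all(dim(curves_a) == dim(curves_b)),
              "conditions differ in shape")
  if (!is.null(rownames(curves_a)) && !is.null(rownames(curves_b))) {
    assert_that(setequal(rownames(curves_a), rownames(curves_b)),
                "participant sets differ between conditions (pairing error)")
    curves_b <- curves_b[rownames(curves_a), , drop = FALSE]
  }
  d <- curves_a - curves_b
  n <- nrow(d)
  mu <- colMeans(d)
  sdv <- apply(d, 2, sd)
  t_field <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  list(t_field = t_field, df = n - 1L, diffs = d,
       flagged_nodes = which(sdv == 0))
}

#' Estimate field smoothness (FWHM) from residuals
#'
#' Residual fields are scaled to unit variance per node; the mean squared
#' node-to-node gradient `v` of the normalised residuals gives
#' `FWHM = sqrt(4 ln 2 / v)` in nodes. Unit-variance white noise has
#' gradient variance 2, hence FWHM ~ 1.18; a linear (perfectly smooth)
#' field gives a very large FWHM. Zero-variance nodes are excluded with a
#' warning.
#'
#' @param residuals Observations x nodes matrix (e.g. paired differences
#'   minus their node means).
#' @return FWHM in nodes (capped below at 1e-3).
#' @export
estimate_fwhm <- function(residuals) {
  residuals <- as.matrix(residuals)
  assert_that(nrow(residuals) >= 2, "need at least 2 residual fields")
  sdv <- apply(residuals, 2, sd)
  keep <- sdv > 0
  if (!all(keep))
    warn(sprintf("%d zero-variance node(s) excluded from FWHM estimate",
                 sum(!keep)))
  assert_that(sum(keep) >= 2, "residuals are constant at every node")
  z <- sweep(residuals[, keep, drop = FALSE], 2, sdv[keep], `/`)
  grad <- z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]
  v <- mean(grad^2)
  if (v <= 0) return(Inf)
  max(sqrt(4 * log(2) / v), 1e-3)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' Solves for the height `u` at which the expected Euler characteristic of
#' the thresholded field matches the requested family-wise alpha:
#' `alpha_tail = 1 - exp(-(rho0(u) + R1 * rho1(u)))` with
#' `R1 = (n_nodes - 1) / fwhm` resels, `rho0(u)` the upper-tail t
#' probability, and
#' `rho1(u) = sqrt(4 ln 2) / (2 pi) * (1 + u^2 / nu)^(-(nu - 1)/2)`.
#' For a two-sided test (the default) alpha is split across tails inside
#' `rho0`. Monotone bisection on `u` in `[0.5, 50]` to 1e-6; the zero-resel
#' limit recovers the scalar t quantile.
#'
#' @param df Degrees of freedom (>= 2).
#' @param fwhm Field smoothness, nodes (> 0).
#' @param n_nodes Field length (default 101).
#' @param alpha Family-wise level in (0, 1).
#' @param two_sided Split alpha across tails?
#' @return Critical t value (> 0).
#' @export
rft_threshold <- function(df, fwhm, n_nodes = 101, alpha = 0.05,
                          two_sided = TRUE) {
  assert_that(df >= 2, "df must be >= 2")
  assert_that(fwhm > 0, "fwhm must be > 0")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  target <- if (two_sided) alpha / 2 else alpha
  r1 <- (n_nodes - 1) / fwhm
  ec_prob <- function(u) {
    rho0 <- pt(u, df, lower.tail = FALSE)
    rho1 <- sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
    1 - exp(-(rho0 + r1 * rho1))
  }
  lo <- 0.5; hi <- 50
  if (ec_prob(lo) < target || ec_prob(hi) > target)
    abort(sprintf(paste0("no RFT root in bracket [0.5, 50]: ",
                         "P(0.5) = %.4g, P(50) = %.4g, target %.4g"),
                  ec_prob(lo), ec_prob(hi), target))
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (ec_prob(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sign-flip permutation threshold for a paired t-field
#'
#' Nonparametric oracle for [rft_threshold()]: the participant difference
#' fields are sign-flipped, the maximum over nodes of |t| is recorded per
#' permutation, and the threshold is the (1 - alpha) quantile of that
#' max-t distribution. When `2^n` does not exceed `n_perm`, all sign
#' patterns are enumerated exhaustively. Deterministic given `seed`.
#'
#' @param diffs Participants x nodes matrix of paired differences.
#' @param alpha Family-wise level.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @return Critical |t| value.
#' @export
permutation_threshold <- function(diffs, alpha = 0.05, n_perm = 10000,
                                  seed = 1L) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  assert_that(n >= 5, "need at least 5 participants for permutation")
  exhaustive <- n <= 30 && 2^n <= n_perm
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed,
              matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                     nrow = n_perm, ncol = n))
  }
  # per node: sum d_i^2 is invariant under sign flips
  ss <- colSums(diffs^2)
  sums <- signs %*% diffs                     # n_perm x nodes
  mu <- sums / n
  sd2 <- (matrix(ss, nrow(sums), length(ss), byrow = TRUE) - n * mu^2) /
    (n - 1)
  tmat <- abs(mu / sqrt(pmax(sd2, 0) / n))
  tmat[!is.finite(tmat)] <- 0
  maxt <- apply(tmat, 1, max)
  as.numeric(quantile(maxt, probs = 1 - alpha, type = 1))
}

#' Suprathreshold clusters of a t-field
#'
#' Maximal runs of nodes where |t| exceeds the critical threshold.
#'
#' @param t_field Length-101 t values (NA treated as subthreshold).
#' @param t_critical Threshold (> 0).
#' @return Tibble: `start_pct`, `end_pct`, `max_abs_t`, `sign`.
#' @export
spm_clusters <- function(t_field, t_critical) {
  above <- !is.na(t_field) & abs(t_field) > t_critical
  if (!any(above))
    return(tibble(start_pct = numeric(0), end_pct = numeric(0),
                  max_abs_t = numeric(0), sign = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  purrr::map_dfr(keep, function(k) {
    idx <- starts[k]:ends[k]
    pk <- idx[which.max(abs(t_field[idx]))]
    tibble(start_pct = idx[1] - 1, end_pct = idx[length(idx)] - 1,
           max_abs_t = abs(t_field[pk]), sign = sign(t_field[pk]))
  })
}

#' One-dimensional SPM paired comparison
#'
#' The full statistical-parametric-mapping chain for one substrate pair and
#' one variable: paired t-field from participant-mean curves, residual
#' smoothness (FWHM) and resel count, critical threshold by random field
#' theory (default) or sign-flip permutation, and suprathreshold clusters.
#' `bonferroni_m` divides alpha before thresholding (e.g. 6 pairwise
#' substrate comparisons).
#'
#' @param curves_a,curves_b Participants x 101 matrices (participant means).
#' @param alpha Nominal family-wise level (default 0.05).
#' @param bonferroni_m Number of comparisons alpha is split across.
#' @param method `"rft"` or `"permutation"`.
#' @param n_perm,seed Permutation settings.
#' @param comparison Label carried into the result.
#' @return Object of class `sandgait_spm`: `t_field`, `df`, `fwhm`,
#'   `resels`, `alpha_effective`, `t_critical`, `clusters`, `comparison`,
#'   `method`.
#' @export
spm_compare <- function(curves_a, curves_b, alpha = 0.05, bonferroni_m = 1,
                        method = c("rft", "permutation"), n_perm = 10000,
                        seed = 1L, comparison = "a_vs_b") {
  method <- match.arg(method)
  tt <- spm_paired_t(curves_a, curves_b)
  resid <- sweep(tt$diffs, 2, colMeans(tt$diffs))
  fwhm <- estimate_fwhm(resid)
  alpha_eff <- alpha / bonferroni_m
  n_nodes <- length(tt$t_field)
  t_crit <- if (method == "rft") {
    rft_threshold(tt$df, fwhm, n_nodes = n_nodes, alpha = alpha_eff)
  } else {
    permutation_threshold(tt$diffs, alpha = alpha_eff, n_perm = n_perm,
                          seed = seed)
  }
  structure(
    list(t_field = tt$t_field, df = tt$df, fwhm = fwhm,
         resels = (n_nodes - 1) / fwhm, alpha_effective = alpha_eff,
         t_critical = t_crit,
         clusters = spm_clusters(tt$t_field, t_crit),
         comparison = comparison, method = method,
         flagged_nodes = tt$flagged_nodes),
    class = "sandgait_spm")
}

#' @export
print.sandgait_spm <- function(x, ...) {
  cat(sprintf("<sandgait_spm %s> df = %d, FWHM = %.1f nodes, t* = %.3f (%s, alpha_eff = %.4g)\n",
              x$comparison, x$df, x$fwhm, x$t_critical, x$method,
              x$alpha_effective))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %g-%g%% cycle, max |t| = %.2f\n", i,
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$max_abs_t[i]))
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}
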