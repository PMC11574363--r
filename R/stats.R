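#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' Standard one-way ANOVA (`F = MS_between / MS_within`) followed by Tukey's
#' honestly-significant-difference pairwise comparisons (studentized-range
#' p-values via R's `TukeyHSD`). Identical values in every group return
#' `F = 0, p = 1` rather than `NaN`.
#'
#' @param data A tidy table.
#' @param value Name of the value column.
#' @param group Name of the grouping column (>= 2 groups, >= 2 values
#'   each).
#' @return Object of class `sandgait_anova`: `f`, `df_between`,
#'   `df_within`, `p`, and `tukey` (tibble: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
anova_tukey <- function(data, value, group) {
  df <- tibble(y = data[[value]], g = factor(data[[group]]))
  df <- df[complete.cases(df), ]
  counts <- table(df$g)
  assert_that(length(counts) >= 2, "need at least 2 groups")
  assert_that(all(counts >= 2), "need at least 2 values per group")
  if (var(df$y) == 0) {
    pairs <- utils::combn(levels(df$g), 2)
    tk <- tibble(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                 diff = 0, lwr = 0, upr = 0, p_adj = 1)
    return(structure(list(f = 0, df_between = length(counts) - 1L,
                          df_within = nrow(df) - length(counts),
                          p = 1, tukey = tk),
                     class = "sandgait_anova"))
  }
  fit <- aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  structure(
    list(f = an[["F value"]][1],
         df_between = an[["Df"]][1], df_within = an[["Df"]][2],
         p = an[["Pr(>F)"]][1],
         tukey = tibble(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"])),
    class = "sandgait_anova")
}

#' @export
print.sandgait_anova <- function(x, ...) {
  cat(sprintf("<sandgait_anova> F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f, x$p))
  print(x$tukey)
  invisible(x)
}

#' Spearman correlogram with first-principal-component ordering
#'
#' Pairwise Spearman rank correlations (average ranks for ties) with
#' p-values from the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))`, and a variable ordering by the
#' first principal component of the correlation matrix: the leading
#' eigenvector of rho (sign fixed so its largest-magnitude entry is
#' positive), variables sorted by descending loading. Constant variables
#' get `NA` correlations and are flagged.
#'
#' @param data A tidy table of one row per trial (trial means).
#' @param vars Character vector of >= 2 variable columns; >= 5 rows
#'   required.
#' @return Object of class `sandgait_corr`: `rho`, `p` (matrices),
#'   `order` (character), `n`, `flagged` (constant variables).
#' @export
spearman_correlogram <- function(data, vars) {
  assert_that(length(vars) >= 2, "need at least 2 variables")
  x <- as.matrix(data[vars])
  assert_that(nrow(x) >= 5, "need at least 5 trials")
  const <- apply(x, 2, function(v) var(v, na.rm = TRUE) == 0 ||
                   all(is.na(v)))
  rho <- suppressWarnings(cor(x, method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[const, ] <- NA_real_; rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  n <- colSums(!is.na(x))
  npair <- outer(n, n, pmin)
  tstat <- rho * sqrt((npair - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * pt(abs(tstat), npair - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  ok <- !const
  ord <- vars
  if (sum(ok) >= 2) {
    sub <- rho[ok, ok, drop = FALSE]
    ev <- eigen(sub, symmetric = TRUE)$vectors[, 1]
    if (ev[which.max(abs(ev))] < 0) ev <- -ev
    ord <- c(colnames(sub)[order(-ev)], vars[const])
  }
  structure(list(rho = rho, p = p, order = ord, n = nrow(x),
                 flagged = vars[const]),
            class = "sandgait_corr")
}

#' @export
print.sandgait_corr <- function(x, ...) {
  cat(sprintf("<sandgait_corr> %d variables, n = %d trials\n",
              ncol(x$rho), x$n))
  cat("  PC1 order:", paste(x$order, collapse = ", "), "\n")
  if (length(x$flagged))
    cat("  flagged constant:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Linear mixed-effect model with participant random intercepts
#'
#' REML fit of `response ~ fixed effects + (1 | participant)` (delegated to
#' `lmerTest`/`lme4`, with Satterthwaite degrees of freedom for the
#' fixed-effect p-values). Singular fits are flagged and the participant
#' variance component reported as fitted (typically 0).
#'
#' @param data Stride or trial table.
#' @param response Response column name (non-constant).
#' @param fixed Character vector of fixed-effect terms (default substrate,
#'   sex and speed).
#' @param interactions Optional character vector of interaction terms
#'   (e.g. `"substrate_id:sex"`).
#' @param participant Random-intercept grouping column.
#' @return Object of class `sandgait_lmm`: `fit`, `fixed` (tibble: term,
#'   estimate, se, df, statistic, p_value), `varcomp` (participant and
#'   residual variances), `singular`, `formula`.
#' @export
fit_lmm <- function(data, response, fixed = c("substrate_id", "sex", "speed"),
                    interactions = NULL, participant = "participant_id") {
  assert_that(length(unique(data[[participant]])) >= 2,
              "need at least 2 participants")
  assert_that(var(as.numeric(data[[response]]), na.rm = TRUE) > 0,
              "response is constant")
  fixed <- fixed[vapply(fixed, function(f)
    length(unique(data[[f]])) > 1, logical(1))]
  rhs <- paste(c(fixed, interactions, sprintf("(1 | %s)", participant)),
               collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble(
    component = c("participant", "residual"),
    variance = c(vc$vcov[vc$grp == participant][1] %||% 0,
                 vc$vcov[vc$grp == "Residual"][1]))
  structure(
    list(fit = fit,
         fixed = tibble(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], df = co[, "df"],
                        statistic = co[, "t value"],
                        p_value = co[, "Pr(>|t|)"]),
         varcomp = varcomp, singular = singular, formula = fml),
    class = "sandgait_lmm")
}

#' @export
print.sandgait_lmm <- function(x, ...) {
  cat("<sandgait_lmm>", deparse(x$formula), "\n")
  if (x$singular) cat("  (singular fit)\n")
  print(x$fixed)
  print(x$varcomp)
  invisible(x)
}
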