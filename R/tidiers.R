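#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SPM comparison
#'
#' One row per gait-cycle node with the t value and whether it exceeds the
#' critical threshold.
#' @param x A `sandgait_spm`.
#' @param ... Unused.
#' @return A tibble: `node`, `t`, `significant`.
#' @export
tidy.sandgait_spm <- function(x, ...) {
  tibble(node = seq_along(x$t_field) - 1, t = x$t_field,
         significant = !is.na(x$t_field) & abs(x$t_field) > x$t_critical)
}

#' @rdname tidy.sandgait_spm
#' @return For `glance`: a one-row tibble with `df`, `fwhm`, `resels`,
#'   `t_critical`, `alpha_effective`, `n_clusters`, `method`.
#' @export
glance.sandgait_spm <- function(x, ...) {
  tibble(comparison = x$comparison, df = x$df, fwhm = x$fwhm,
         resels = x$resels, t_critical = x$t_critical,
         alpha_effective = x$alpha_effective,
         n_clusters = nrow(x$clusters), method = x$method)
}

#' Tidy ANOVA + Tukey results
#' @param x A `sandgait_anova`.
#' @param ... Unused.
#' @return The pairwise Tukey table (`pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
tidy.sandgait_anova <- function(x, ...) x$tukey

#' @rdname tidy.sandgait_anova
#' @export
glance.sandgait_anova <- function(x, ...) {
  tibble(f = x$f, df_between = x$df_between, df_within = x$df_within,
         p_value = x$p)
}

#' Tidy a Spearman correlogram
#' @param x A `sandgait_corr`.
#' @param ... Unused.
#' @return Long tibble of unique pairs: `var1`, `var2`, `rho`, `p_value`.
#' @export
tidy.sandgait_corr <- function(x, ...) {
  vars <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
         rho = x$rho[idx], p_value = x$p[idx])
}

#' Tidy a mixed-model fit
#' @param x A `sandgait_lmm`.
#' @param ... Unused.
#' @return The fixed-effect table (`term`, `estimate`, `se`, `df`,
#'   `statistic`, `p_value`).
#' @export
tidy.sandgait_lmm <- function(x, ...) x$fixed

#' @rdname tidy.sandgait_lmm
#' @export
glance.sandgait_lmm <- function(x, ...) {
  tibble(sigma_participant = sqrt(x$varcomp$variance[1]),
         sigma_residual = sqrt(x$varcomp$variance[2]),
         singular = x$singular,
         reml_criterion = as.numeric(lme4::REMLcrit(x$fit)))
}
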