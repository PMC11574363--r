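#' Plot an SPM t-field with its critical threshold
#'
#' The t statistic across the gait cycle with horizontal dashed lines at
#' +/- the critical threshold and shaded suprathreshold regions.
#'
#' @param object A `sandgait_spm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sandgait_spm <- function(object, ...) {
  df <- tidy.sandgait_spm(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$t_critical,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% gait cycle", y = "SPM{t}",
                  title = object$comparison,
                  subtitle = sprintf("t* = %.2f (%s)", object$t_critical,
                                     object$method)) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters))
    p <- p + ggplot2::geom_rect(
      data = object$clusters, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_pct, xmax = .data$end_pct,
                   ymin = -Inf, ymax = Inf), alpha = 0.15, fill = "red")
  p
}

#' Distribution plots of spatiotemporal parameters by substrate
#'
#' Box plots of per-stride parameters split by substrate, one facet per
#' variable.
#'
#' @param stride_table A stride table (e.g. from
#'   [compute_spatiotemporal()]).
#' @param vars Variables to plot.
#' @return A ggplot.
#' @export
plot_stride_distributions <- function(stride_table,
                                      vars = c("speed", "stride_length",
                                               "cycle_time", "stance_time",
                                               "swing_time", "duty_factor")) {
  long <- tidyr::pivot_longer(stride_table, all_of(vars),
                              names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$substrate_id,
                                     y = .data$value,
                                     fill = .data$substrate_id)) +
    ggplot2::geom_boxplot(outlier.colour = "red", outlier.size = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1),
                   legend.position = "none")
}

#' Mean energy curves over the gait cycle by substrate
#'
#' Group-mean (with a ribbon of +/- 1 s.e.) of per-stride energy curves
#' normalised to 101 nodes.
#'
#' @param curves Long curve tibble (`substrate_id`, `variable`, `node`,
#'   `value`), e.g. from [stride_energetics()] with `keep_curves = TRUE`.
#' @return A ggplot.
#' @export
plot_energy_curves <- function(curves) {
  summ <- curves |>
    group_by(.data$substrate_id, .data$variable, .data$node) |>
    summarise(mean = mean(.data$value), se = sd(.data$value) / sqrt(n()),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$node, y = .data$mean,
                                     colour = .data$substrate_id,
                                     fill = .data$substrate_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "% gait cycle", y = "Energy (J)") +
    ggplot2::theme_minimal()
}

#' Correlogram heat map ordered by the first principal component
#'
#' @param x A `sandgait_corr`.
#' @param alpha Mark cells with p below this level.
#' @return A ggplot.
#' @export
plot_correlogram <- function(x, alpha = 0.05) {
  ord <- x$order
  df <- tidy.sandgait_corr(x) |>
    mutate(var1 = factor(.data$var1, levels = ord),
           var2 = factor(.data$var2, levels = rev(ord)),
           sig = !is.na(.data$p_value) & .data$p_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = function(d) d[d$sig, ], size = 0.6) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white",
                                  high = "blue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean normalised EMG curves by substrate
#'
#' @param curves nEMG curve tibble from [process_emg()].
#' @return A ggplot.
#' @export
plot_nemg_curves <- function(curves) {
  summ <- curves |>
    group_by(.data$substrate_id, .data$muscle, .data$node) |>
    summarise(mean = mean(.data$nemg), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$node, y = .data$mean,
                                     colour = .data$substrate_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "% gait cycle", y = "nEMG") +
    ggplot2::theme_minimal()
}
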