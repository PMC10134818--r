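#' Plot fold-change trajectories
#'
#' Log2-scale fold changes over the time course, one line per metabolite,
#' with significant points emphasised when significance flags are present.
#'
#' @param fct A `fold_change_table` with `timepoint_min`.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(fct) {
  stopifnot("timepoint_min" %in% names(fct))
  p <- ggplot2::ggplot(fct,
    ggplot2::aes(x = .data$timepoint_min, y = .data$log2_fc,
                 colour = .data$metabolite_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minutes post-induction",
                  y = expression(log[2] ~ "fold change vs pre-induction"),
                  colour = NULL) +
    ggplot2::facet_wrap(~strain)
  if ("significant" %in% names(fct)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(fct, .data$significant %in% TRUE),
      shape = 8, size = 3, show.legend = FALSE)
  }
  p
}

#' @method autoplot fold_change_table
#' @export
autoplot.fold_change_table <- function(object, ...) {
  if ("timepoint_min" %in% names(object)) return(plot_fold_changes(object))
  ggplot2::ggplot(object,
    ggplot2::aes(x = stats::reorder(.data$metabolite_id, .data$log2_fc),
                 y = .data$log2_fc)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "fold change vs control")) +
    ggplot2::facet_wrap(~strain)
}

#' Plot pool totals
#'
#' @param pools Tibble from [pool_summary_table()].
#' @return A ggplot object (log10 molarity scale).
#' @export
plot_pools <- function(pools) {
  ggplot2::ggplot(pools,
    ggplot2::aes(x = stats::reorder(.data$pool, .data$total_M),
                 y = .data$total_M)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "summed pool concentration (M)")
}

#' @method autoplot dg_table
#' @export
autoplot.dg_table <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$dg_in_vivo))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reaction, y = .data$dg_in_vivo)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dg_in_vivo - .data$dg_se,
                   ymax = .data$dg_in_vivo + .data$dg_se), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(Delta * G["in vivo"] ~ "(kJ/mol)"))
}

#' @method autoplot bottleneck_scores
#' @export
autoplot.bottleneck_scores <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = stats::reorder(.data$reaction, .data$score_bits),
                 y = .data$score_bits, fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = 2, colour = "grey50") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "accumulation score (bits)", fill = NULL)
}

#' Plot a growth series with its fitted exponential window
#'
#' @param growth Tibble `time_h`, `od600`.
#' @param fit Optional `growth_fit`; computed if absent.
#' @return A ggplot object (log OD scale).
#' @export
plot_growth <- function(growth, fit = NULL) {
  if (is.null(fit)) fit <- fit_growth_rate(growth)
  ggplot2::ggplot(growth, ggplot2::aes(x = .data$time_h, y = .data$od600)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::annotate("rect", xmin = fit$window_h[1], xmax = fit$window_h[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "steelblue") +
    ggplot2::labs(x = "time (h)", y = "OD600",
                  subtitle = sprintf("mu = %.3f /h", fit$mu_per_h))
}
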