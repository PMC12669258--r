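#' Plot a feedback trace
#'
#' Raw coverage, smoothed score, and the emitted feedback value over the
#' session, faceted by block.
#'
#' @param object An `msnf_trace` from [run_session()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msnf_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("raw_coverage", "smoothed_score", "feedback"),
    names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~block, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a calibration distribution
#'
#' Histogram of epoch-wise target-state coverage with the mean and the
#' one-standard-deviation feedback thresholds.
#'
#' @param object An `msnf_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msnf_calibration <- function(object, ...) {
  ggplot2::ggplot(object$coverages, ggplot2::aes(.data$coverage)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$min_threshold, object$mu,
                                       object$max_threshold),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(
      x = sprintf("state %s coverage per epoch", object$target_state),
      y = "epochs") +
    ggplot2::theme_minimal()
}

#' Plot microstate metrics
#'
#' One panel per metric (GEV, time coverage, mean duration), one bar per
#' state.
#'
#' @param object An `msnf_metrics` tibble from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msnf_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("gev", "time_coverage", "mean_duration_ms"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$state, .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "microstate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Paired estimation plot
#'
#' A Gardner-Altman-style panel: paired observations connected per subject
#' next to the effect size with its BCa confidence interval.
#'
#' @param object An `msnf_estimation` from [paired_estimation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msnf_estimation <- function(object, ...) {
  d <- object$data
  long <- tibble::tibble(
    subject = rep(seq_len(nrow(d)), 2),
    condition = rep(c("1", "2"), each = nrow(d)),
    value = c(d$x, d$y)
  )
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$value,
                                           group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
  eff <- tibble::tibble(d = object$d, lo = object$ci_low, hi = object$ci_high)
  p2 <- ggplot2::ggplot(eff, ggplot2::aes(x = "paired d", y = .data$d)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "effect size") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, widths = c(2, 1))
}
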