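#' Plot a pooled cumulative incidence curve
#'
#' @param object An `fgmi_pooled_cif`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fgmi_pooled_cif
#' @export
autoplot.fgmi_pooled_cif <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time", y = "Cumulative incidence") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot pooled coefficients with confidence intervals
#'
#' @param object An `fgmi_pooled`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fgmi_pooled
#' @export
autoplot.fgmi_pooled <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Log subdistribution hazard ratio", y = NULL)
}

#' Plot relative bias per method from a performance summary
#'
#' @param perf Output of [summarize_performance()].
#' @param term Which coefficient to display.
#' @return A ggplot with 95% Monte-Carlo intervals.
#' @export
plot_relative_bias <- function(perf, term = "X") {
  d <- perf[perf$term == term, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_bias_pct, y = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$rel_bias_pct - 1.96 * .data$rel_bias_pct_mcse,
                   xmax = .data$rel_bias_pct + 1.96 * .data$rel_bias_pct_mcse),
      height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Relative bias (%)", y = NULL)
}
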