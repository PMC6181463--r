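# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort trace
#'
#' State occupancy over the monthly cycles, one line per health state.
#'
#' @param object A `cohort_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                               colour = .data$state)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Cycle (months)", y = "Occupancy",
                  colour = "Health state") +
    ggplot2::theme_minimal()
}

#' Plot PSA outcome distributions
#'
#' Histogram of the Monte Carlo samples per outcome, with the point
#' estimate (solid) and credibility bounds (dashed) marked.
#'
#' @param object A `psa_result` from [run_psa()].
#' @param outcomes Optional character vector restricting which outcomes to
#'   show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psa_result <- function(object, outcomes = NULL, ...) {
  samples <- object$samples
  summary <- object$summary
  if (!is.null(outcomes)) {
    samples <- dplyr::filter(samples, .data$outcome %in% outcomes)
    summary <- dplyr::filter(summary, .data$outcome %in% outcomes)
  }
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = summary,
                        ggplot2::aes(xintercept = .data$point)) +
    ggplot2::geom_vline(data = summary,
                        ggplot2::aes(xintercept = .data$bci_low),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = summary,
                        ggplot2::aes(xintercept = .data$bci_high),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::labs(x = "Outcome value", y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Tornado plot for one-way sensitivity analysis
#'
#' Horizontal bars spanning each parameter's low-to-high outcome range
#' around the base-case value, ordered by swing.
#'
#' @param tornado A tibble from [tornado_table()].
#' @return A ggplot.
#' @export
plot_tornado <- function(tornado) {
  stopifnot(all(c("parameter", "value_low", "value_high", "swing") %in%
                  names(tornado)))
  tornado <- dplyr::mutate(
    tornado,
    parameter = factor(.data$parameter,
                       levels = rev(tornado$parameter[order(-tornado$swing)])))
  ggplot2::ggplot(tornado,
                  ggplot2::aes(y = .data$parameter,
                               xmin = pmin(.data$value_low, .data$value_high),
                               xmax = pmax(.data$value_low, .data$value_high))) +
    ggplot2::geom_linerange(linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$value_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "Outcome", y = NULL) +
    ggplot2::theme_minimal()
}
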