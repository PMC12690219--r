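#' Cost-effectiveness plane with the efficiency frontier
#'
#' Strategies as points in the (QALY, cost) plane; the frontier as a line
#' through its members; optionally the willingness-to-pay threshold as a
#' reference slope through the cheapest strategy.
#'
#' @param object An `osteo_cea` from [frontier()].
#' @param wtp Optional willingness-to-pay slope ($/QALY) to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot osteo_cea
#' @export
autoplot.osteo_cea <- function(object, wtp = NULL, ...) {
  fr <- object[object$on_frontier, ]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = fr, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dominance),
                        size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Discounted QALYs", y = "Discounted cost (USD)",
                  colour = "Dominance") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    anchor <- fr[which.min(fr$cost), ]
    p <- p + ggplot2::geom_abline(slope = wtp,
                                  intercept = anchor$cost -
                                    wtp * anchor$qaly,
                                  colour = "grey60")
  }
  p
}

#' Cost-effectiveness acceptability curves
#'
#' Probability that each strategy is optimal (highest net monetary
#' benefit) as a function of the willingness-to-pay threshold.
#'
#' @param object An `osteo_ceac` from [psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot osteo_ceac
#' @export
autoplot.osteo_ceac <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity analyses
#'
#' Horizontal bars spanning the ICER obtained at each parameter's lower
#' and upper bound, sorted by bar width, with the base-case ICER as a
#' dashed reference line.
#'
#' @param object An `osteo_tornado` from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot osteo_tornado
#' @export
autoplot.osteo_tornado <- function(object, ...) {
  dat <- mutate(as_tibble(object),
                parameter = factor(.data$parameter,
                                   levels = rev(.data$parameter)))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Simulated survival and cumulative fracture incidence
#'
#' @param object An `osteo_outcome` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object with overall survival and cumulative
#'   any-fracture incidence by year.
#' @method autoplot osteo_outcome
#' @export
autoplot.osteo_outcome <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$survival, series = "Overall survival",
           value = .data$surviving, .keep = "unused"),
    mutate(object$cumulative_fracture, series = "Any fracture (cumulative)",
           value = .data$incidence, .keep = "unused"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years since AI initiation", y = "Proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
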