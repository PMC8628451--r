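#' Cost-effectiveness plane
#'
#' Scatter of PSA draws on the (incremental QALYs, incremental cost) plane,
#' with the origin marked; the quadrants read as usual (upper right: more
#' effective and more costly, lower right: dominant, ...). An optional
#' willingness-to-pay line separates cost-effective draws.
#'
#' @param samples A `psa_samples` object from [psa()].
#' @param lambda Optional willingness-to-pay per QALY; drawn as a line
#'   through the origin.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(samples, lambda = NULL) {
  stopifnot(inherits(samples, "psa_samples"))
  d <- samples$draws
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  if (!is.null(lambda)) {
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0,
                                  linetype = "dashed")
  }
  p
}

#' Cost-effectiveness acceptability curve
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the outcome at each parameter's low and high
#' bound, widest on top, around the base-case outcome.
#'
#' @param tornado A `tornado` data frame from [owsa()].
#' @param top Show only the `top` widest bars (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = nrow(tornado)) {
  stopifnot(inherits(tornado, "tornado"))
  d <- utils::head(as.data.frame(tornado), top)
  d$name <- factor(d$name, levels = rev(d$name))
  d$lo <- pmin(d$outcome_low, d$outcome_high)
  d$hi <- pmax(d$outcome_low, d$outcome_high)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$name), linewidth = 4,
                          colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "base_outcome"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Outcome", y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Parameter-sweep curve
#'
#' @param sweep A `parameter_sweep` from [parameter_sweep()].
#' @param outcome Column of the sweep to plot (default incremental savings,
#'   `-delta_cost`).
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, outcome = "savings", xlab = "Parameter value") {
  stopifnot(inherits(sweep, "parameter_sweep"))
  d <- as.data.frame(sweep)
  d$savings <- -d$delta_cost
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data[[outcome]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = outcome, title = "Parameter sweep") +
    ggplot2::theme_minimal()
}
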