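# ggplot2 graphics. Plots are cosmetic companions to the tested statistics:
# the tested contract is the numbers, not the rendering.

#' Plot a vowel system in the conventional F2-by-F1 chart
#'
#' Axes are reversed so the chart reads like an articulatory vowel diagram:
#' high front vowels top-left, low back vowels bottom-right.
#'
#' @param data Formant tibble; if it holds several systems, pass `sample` to
#'   pick one.
#' @param sample Optional `sample_id` to plot.
#' @param bark Plot on the Bark scale instead of Hz.
#' @return A ggplot object.
#' @export
plot_vowel_system <- function(data, sample = NULL, bark = FALSE) {
  vd_require_columns(data, c("vowel", "f1", "f2"), "plot_vowel_system")
  if (!is.null(sample)) data <- data[data$sample_id == sample, ]
  if (bark) {
    data <- add_bark(data)
    xvar <- "b2"; yvar <- "b1"
    labs <- ggplot2::labs(x = "B2 (Bark)", y = "B1 (Bark)")
  } else {
    xvar <- "f2"; yvar <- "f1"
    labs <- ggplot2::labs(x = "F2 (Hz)", y = "F1 (Hz)")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                     label = .data$vowel)) +
    ggplot2::geom_text() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    labs +
    ggplot2::theme_minimal()
}

#' Scatter of the log-log dependence with the fitted line
#'
#' @param object A `vowel_ols` fit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vowel_ols <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope_k,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(x = "log10(Effective DE)", y = "log10(FE)",
                  subtitle = sprintf("K = %.3f, adj. R2 = %.3f, n = %d",
                                     object$slope_k, object$adj_r2,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Group-mean regression plot with error bars
#'
#' @param object A `vowel_grouped` fit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vowel_grouped <- function(object, ...) {
  p <- object$points
  ggplot2::ggplot(p, ggplot2::aes(x = .data$x, y = .data$y,
                                  label = .data$stratum)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$se_y,
                                        ymax = .data$y + .data$se_y),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x - .data$se_x,
                                         xmax = .data$x + .data$se_x),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::geom_abline(slope = object$slope_k,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(x = "mean log10(Effective DE)", y = "mean log10(FE)") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of stratified slopes
#'
#' One point per stratum: the fitted power-law slope with a 2-SE interval.
#'
#' @param object A `vowel_stratified` report.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vowel_stratified <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$slope_k, y = .data$stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$slope_k - 2 * .data$se_slope,
                   xmax = .data$slope_k + 2 * .data$se_slope),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "slope K (+/- 2 SE)", y = object$stratum) +
    ggplot2::theme_minimal()
}
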