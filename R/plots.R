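#' Plot an A260 trace with detected peaks
#'
#' @param trace An [a260_trace()].
#' @param peaks Optional peak times to mark (e.g. from [find_peaks()]).
#' @return A ggplot object.
#' @export
plot_a260 <- function(trace, peaks = NULL) {
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$time_s,
                                    y = .data$absorbance_au)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "elution time (s)", y = "A260 (AU)")
  if (!is.null(peaks) && length(peaks) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = peaks, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' @export
autoplot.ribosome_calibration <- function(object, ...) {
  pts <- tibble(log_time = log(object$peak_times), count = object$counts)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_time, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$alpha, slope = object$beta) +
    ggplot2::labs(x = "ln(peak elution time)", y = "ribosome count",
                  title = sprintf("k = %.3f + %.3f ln(t)", object$alpha,
                                  object$beta))
}

#' @export
autoplot.dye_calibration <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dotted") +
    ggplot2::xlim(-4, 4) + ggplot2::ylim(-4, 4) +
    ggplot2::labs(x = "expected log2 ratio", y = "measured log2 ratio",
                  title = sprintf("measured = %.3f expected + %.3f (r2 %.3f)",
                                  object$slope, object$intercept,
                                  object$r_squared))
}

#' Translation change versus mRNA abundance change
#'
#' Scatter of gene-level changes with significant translation calls
#' highlighted and vertical lines at +/- `sd_multiple` SD of the abundance
#' changes — the display used to judge which significant translation changes
#' occur without a corresponding abundance change.
#'
#' @param translation A [diff_translation()] tibble.
#' @param abundance Tibble with `gene_id`, `log2_change`.
#' @param sd_multiple Width of the abundance band in SDs (default 1).
#' @return A ggplot object.
#' @export
plot_translation_vs_abundance <- function(translation, abundance,
                                          sd_multiple = 1) {
  df <- dplyr::inner_join(translation, abundance, by = "gene_id")
  mu <- mean(df$log2_change)
  sigma <- sd(df$log2_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_change,
                                   y = .data$mean_change,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = mu + c(-1, 1) * sd_multiple * sigma,
                        colour = "purple", linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 change in mRNA abundance",
                  y = "log2 change in translation",
                  colour = "significant")
}
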