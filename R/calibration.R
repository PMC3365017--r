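#' Calibrate elution time to average ribosome number
#'
#' Successive A260 peaks in a polysome gradient correspond to mRNAs carrying
#' 1, 2, 3, ... ribosomes, and the peaks compress deeper into the gradient.
#' Fitting ribosome count against the natural log of peak elution time,
#' k = alpha + beta * ln(t), gives a continuous map from any elution time to
#' an average ribosome number.
#'
#' @param peak_times Strictly increasing, positive peak elution times
#'   (seconds), assigned consecutive ribosome counts starting at
#'   `first_count`.
#' @param first_count Ribosome count of the first supplied peak (default 1,
#'   the 80S monosome).
#' @return An object of class `ribosome_calibration` with fields `alpha`,
#'   `beta`, `peak_times`, `counts` and `residual_rms`.
#' @examples
#' calib <- fit_ribosome_calibration(exp((1:6 + 10) / 2.5))
#' time_to_ribosomes(calib, 150)
#' @export
fit_ribosome_calibration <- function(peak_times, first_count = 1L) {
  peak_times <- as.numeric(peak_times)
  if (length(peak_times) < 2) {
    abort("need at least two peaks to calibrate (fit is underdetermined)")
  }
  if (any(peak_times <= 0)) abort("peak times must be positive (log undefined)")
  if (any(diff(peak_times) <= 0)) abort("peak times must be strictly increasing")
  counts <- seq(first_count, length.out = length(peak_times))
  fit <- lm(counts ~ log(peak_times))
  beta <- unname(coef(fit)[2])
  if (!is.finite(beta) || beta <= 0) {
    abort("calibration slope must be positive")
  }
  structure(
    list(
      alpha = unname(coef(fit)[1]),
      beta = beta,
      peak_times = peak_times,
      counts = counts,
      residual_rms = sqrt(mean(fit$residuals^2))
    ),
    class = "ribosome_calibration"
  )
}

#' @export
print.ribosome_calibration <- function(x, ...) {
  cat("<ribosome_calibration> k = ", format(x$alpha, digits = 4), " + ",
      format(x$beta, digits = 4), " * ln(t), ", length(x$peak_times),
      " peaks, residual RMS ", format(x$residual_rms, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_ribosome_calibration
#' @param x,calib A `ribosome_calibration`.
#' @param ... Unused.
#' @export
tidy.ribosome_calibration <- function(x, ...) {
  tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta)
  )
}

#' @rdname fit_ribosome_calibration
#' @export
glance.ribosome_calibration <- function(x, ...) {
  tibble(
    n_peaks = length(x$peak_times),
    first_count = x$counts[1],
    residual_rms = x$residual_rms
  )
}

#' Convert elution time to average ribosome number
#'
#' Evaluates the calibrated map k = alpha + beta * ln(t). The result is
#' continuous, strictly increasing in `t`, and may be below 1 near the top of
#' the gradient; it is never clipped.
#'
#' @param calib A [fit_ribosome_calibration()] result.
#' @param t Elution time(s) in seconds, > 0.
#' @return Average ribosome number(s).
#' @export
time_to_ribosomes <- function(calib, t) {
  stopifnot(inherits(calib, "ribosome_calibration"))
  if (any(t <= 0)) abort("elution time must be positive")
  calib$alpha + calib$beta * log(t)
}

#' Convert average ribosome number to elution time
#'
#' Inverse of [time_to_ribosomes()]: t = exp((k - alpha) / beta). Used by the
#' synthetic generator to place transcripts in the gradient.
#'
#' @inheritParams time_to_ribosomes
#' @param k Average ribosome number(s).
#' @return Elution time(s) in seconds.
#' @export
ribosomes_to_time <- function(calib, k) {
  stopifnot(inherits(calib, "ribosome_calibration"))
  exp((k - calib$alpha) / calib$beta)
}

#' Interpolate fractional gradient position to elution time
#'
#' Linear interpolation between fraction midpoint times; positions below
#' midpoint 1 or above midpoint n extrapolate linearly using the adjacent
#' segment slope.
#'
#' @param position Fractional gradient position(s), 1-based.
#' @param geom A [gradient_geometry()].
#' @return Elution time(s) in seconds.
#' @export
position_to_time <- function(position, geom) {
  mids <- fraction_midpoints(geom)
  interp_linear(seq_along(mids), mids, position)
}

#' Interpolate elution time to fractional gradient position
#'
#' Inverse of [position_to_time()] under the same piecewise-linear map.
#'
#' @param time Elution time(s) in seconds.
#' @param geom A [gradient_geometry()].
#' @return Fractional position(s).
#' @export
time_to_position <- function(time, geom) {
  mids <- fraction_midpoints(geom)
  interp_linear(mids, seq_along(mids), time)
}

# piecewise-linear interpolation with linear extrapolation beyond the knots
interp_linear <- function(x, y, xout) {
  inside <- approx(x, y, xout = xout, rule = 1)$y
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    inside[lo] <- y[1] + slope * (xout[lo] - x[1])
  }
  if (any(hi)) {
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    inside[hi] <- y[n] + slope * (xout[hi] - x[n])
  }
  inside
}
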