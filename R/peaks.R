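#' Find absorbance peaks in an A260 trace
#'
#' Locates local maxima of the absorbance trace whose prominence — height
#' above the higher of the two flanking minima — is at least `min_prominence`
#' times the overall range of the trace. Used to locate the 80S (monosome)
#' peak and successive polysome peaks; restrict `search_window` to start at
#' the 80S region to exclude 40S/60S subunit peaks.
#'
#' @param trace An [a260_trace()] (or a data frame with columns `time_s`,
#'   `absorbance_au`).
#' @param min_prominence Required prominence as a fraction of the trace range,
#'   in (0, 1). Default 0.05.
#' @param search_window Length-2 numeric: time interval searched for peaks.
#'   Defaults to the full trace range.
#' @return Numeric vector of peak times, ascending. May be empty.
#' @examples
#' t <- seq(0, 300, by = 1)
#' y <- dnorm(t, 100, 8) + dnorm(t, 160, 8) + dnorm(t, 205, 8)
#' find_peaks(a260_trace(t, y))
#' @export
find_peaks <- function(trace, min_prominence = 0.05, search_window = NULL) {
  if (!inherits(trace, "a260_trace")) {
    trace <- a260_trace(trace$time_s, trace$absorbance_au)
  }
  if (min_prominence <= 0 || min_prominence >= 1) {
    abort("`min_prominence` must be in (0, 1)")
  }
  times <- trace$time_s
  y <- trace$absorbance_au
  if (is.null(search_window)) search_window <- range(times)
  if (length(search_window) != 2 || search_window[1] >= search_window[2]) {
    abort("`search_window` must be an increasing length-2 interval")
  }
  if (search_window[1] < min(times) || search_window[2] > max(times)) {
    abort("`search_window` must lie within the trace time range")
  }
  threshold <- min_prominence * (max(y) - min(y))
  n <- length(y)
  if (n < 3 || threshold <= 0) return(numeric(0))

  peaks <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(y[i] > y[i - 1] && y[i] >= y[i + 1])) next
    if (times[i] < search_window[1] || times[i] > search_window[2]) next
    # prominence: descend to the lowest point on each side before a higher
    # value is reached; prominence is height above the HIGHER flanking minimum
    left_min <- y[i]
    for (j in (i - 1):1) {
      if (y[j] > y[i]) break
      if (y[j] < left_min) left_min <- y[j]
    }
    right_min <- y[i]
    for (j in (i + 1):n) {
      if (y[j] > y[i]) break
      if (y[j] < right_min) right_min <- y[j]
    }
    if (y[i] - max(left_min, right_min) >= threshold) {
      peaks <- c(peaks, times[i])
    }
  }
  sort(peaks)
}
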