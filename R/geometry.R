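#' Gradient geometry
#'
#' Describes how a sucrose gradient was cut into fractions: `n_fractions`
#' fractions delimited by `n_fractions + 1` strictly increasing elution-time
#' boundaries (seconds), with the top of the gradient (lightest material) at
#' time 0 and fraction 1 at the top.
#'
#' @param boundaries Numeric vector of fraction boundary times in seconds,
#'   strictly increasing, first element >= 0. Supply either `boundaries` or
#'   both `n_fractions` and `total_time`.
#' @param n_fractions Number of equally sized fractions (used with
#'   `total_time` when `boundaries` is missing).
#' @param total_time Total elution time in seconds for equal spacing.
#'
#' @return An object of class `gradient_geometry` with fields `n_fractions`
#'   and `boundaries`.
#' @examples
#' geom <- gradient_geometry(n_fractions = 15, total_time = 450)
#' fraction_midpoints(geom)
#' @export
gradient_geometry <- function(boundaries = NULL, n_fractions = NULL,
                              total_time = NULL) {
  if (is.null(boundaries)) {
    if (is.null(n_fractions) || is.null(total_time)) {
      abort("supply `boundaries`, or `n_fractions` together with `total_time`")
    }
    boundaries <- seq(0, total_time, length.out = n_fractions + 1)
  }
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2) abort("need at least two boundary times")
  if (boundaries[1] < 0) abort("boundaries must start at or after time 0")
  if (any(diff(boundaries) <= 0)) abort("boundaries must be strictly increasing")
  structure(
    list(n_fractions = length(boundaries) - 1L, boundaries = boundaries),
    class = "gradient_geometry"
  )
}

#' @export
print.gradient_geometry <- function(x, ...) {
  cat("<gradient_geometry> ", x$n_fractions, " fractions over [",
      x$boundaries[1], ", ", x$boundaries[length(x$boundaries)], "] s\n",
      sep = "")
  invisible(x)
}

#' Fraction midpoint elution times
#'
#' The midpoint of fraction f is the mean of its two boundary times; these
#' midpoints anchor the map from fractional gradient position to elution time.
#'
#' @param geom A [gradient_geometry()].
#' @return Numeric vector of length `n_fractions`, strictly increasing.
#' @export
fraction_midpoints <- function(geom) {
  stopifnot(inherits(geom, "gradient_geometry"))
  b <- geom$boundaries
  (b[-length(b)] + b[-1]) / 2
}

#' A260 absorbance trace
#'
#' A uniformly sampled absorbance-at-260nm trace recorded during gradient
#' fractionation. Stored as a tibble with columns `time_s` and
#' `absorbance_au`.
#'
#' @param time_s Sampled elution times (seconds), strictly increasing with a
#'   constant step.
#' @param absorbance_au Nonnegative absorbance values (arbitrary units), same
#'   length as `time_s`.
#' @return A tibble with class `a260_trace`.
#' @export
a260_trace <- function(time_s, absorbance_au) {
  time_s <- as.numeric(time_s)
  absorbance_au <- as.numeric(absorbance_au)
  if (length(time_s) == 0) abort("trace is empty")
  if (length(time_s) != length(absorbance_au)) {
    abort("`time_s` and `absorbance_au` must have the same length")
  }
  steps <- diff(time_s)
  if (any(steps <= 0)) abort("trace times must be strictly increasing")
  if (length(steps) > 1 &&
      max(steps) - min(steps) > 1e-6 * max(abs(steps))) {
    abort("trace times must be uniformly spaced")
  }
  if (any(absorbance_au < 0)) abort("absorbance must be nonnegative")
  out <- tibble(time_s = time_s, absorbance_au = absorbance_au)
  class(out) <- c("a260_trace", class(out))
  out
}

#' Read an A260 trace from a tab-delimited file
#'
#' Expects a two-column file with header `time_s` and `absorbance_au`.
#'
#' @param path File path.
#' @return An [a260_trace()] tibble.
#' @export
read_a260_trace <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("time_s", "absorbance_au")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("trace file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  a260_trace(df$time_s, df$absorbance_au)
}

#' Write an A260 trace to a tab-delimited file
#'
#' @param trace An [a260_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_a260_trace <- function(trace, path) {
  readr::write_tsv(trace, path)
  invisible(path)
}
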