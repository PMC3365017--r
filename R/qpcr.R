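#' Read a per-fraction qRT-PCR table
#'
#' Tab-delimited with columns `gene`, `condition`, `fraction`, `mean`, `se`,
#' `control_mean`, `control_se`: triplicate-PCR means and standard errors for
#' the transcript of interest and for the doping control added to every
#' fraction before RNA harvest.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_qpcr_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene", "condition", "fraction", "mean", "se",
            "control_mean", "control_se")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("qPCR table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Normalize a per-fraction qRT-PCR profile
#'
#' Divides each fraction's mean by the doping-control mean for that fraction
#' (relative errors combined in quadrature for the division), then rescales
#' the profile so the normalized values sum to exactly 1 across the gradient.
#' The rescale is treated as exact: it uses the measured totals, so no further
#' error is propagated through it.
#'
#' @param raw Tibble with columns `fraction`, `mean`, `se` for one gene in one
#'   condition (ordered or orderable by `fraction`).
#' @param control Tibble with columns `fraction`, `mean`, `se` for the doping
#'   control; control means must be positive in every fraction.
#' @return A tibble with columns `fraction`, `value` (summing to 1) and `se`
#'   (propagated through the division, scaled with the values).
#' @export
normalize_qpcr_profile <- function(raw, control) {
  raw <- dplyr::arrange(as_tibble(raw), .data$fraction)
  control <- dplyr::arrange(as_tibble(control), .data$fraction)
  if (!identical(raw$fraction, control$fraction)) {
    abort("raw and control tables must cover the same fractions")
  }
  if (any(control$mean <= 0)) {
    bad <- raw$fraction[control$mean <= 0]
    abort(paste0("zero or negative control mean in fraction ",
                 paste(bad, collapse = ", ")))
  }
  if (any(raw$mean < 0)) abort("qPCR means must be nonnegative")
  value <- raw$mean / control$mean
  rel_raw <- ifelse(raw$mean > 0, raw$se / raw$mean, 0)
  rel_ctl <- control$se / control$mean
  rel <- sqrt(rel_raw^2 + rel_ctl^2)
  total <- sum(value)
  if (total <= 0) abort("profile is all zero after control normalization")
  value <- value / total
  tibble(fraction = raw$fraction, value = value, se = value * rel)
}

#' Explicitly encode a qRT-PCR profile
#'
#' Computes the theoretical Cy5/Cy3 ratio that the Gradient Encoding pooling
#' would have produced for a transcript with this per-fraction profile: each
#' fraction's normalized value is multiplied by the proportion of that
#' fraction labeled with each dye, the per-dye amounts are summed across
#' fractions, and their ratio is returned. Identical in form to
#' [pool_profile()], evaluated on qPCR values; this is the independent oracle
#' for the array decode.
#'
#' @param profile A normalized profile from [normalize_qpcr_profile()] (or
#'   any tibble with columns `fraction` and `value`).
#' @param scheme An [encoding_scheme()].
#' @return The theoretical Cy5/Cy3 ratio (linear scale).
#' @export
explicit_encode <- function(profile, scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  profile <- dplyr::arrange(as_tibble(profile), .data$fraction)
  if (nrow(profile) != scheme$n_fractions) {
    abort("profile must cover every fraction of the scheme")
  }
  cy5 <- sum(profile$value * scheme$a)
  cy3 <- sum(profile$value * (1 - scheme$a))
  cy5 / cy3
}

#' Oracle translation change from per-fraction qRT-PCR profiles
#'
#' The explicit-calculation oracle: each condition's normalized qPCR profile
#' is encoded into a theoretical Cy5/Cy3 ratio, expressed as a fractional
#' gradient position using the regression of expected per-fraction ratios on
#' fraction number, converted to an elution time at the fraction midpoints
#' and then to an average ribosome number using that gradient's own peak
#' calibration (gradients are not perfectly superimposable, so each may carry
#' its own calibration). Returns the log2 ratio of treated to untreated
#' average ribosome number.
#'
#' @param treated,untreated Normalized profiles ([normalize_qpcr_profile()]).
#' @param scheme The shared [encoding_scheme()].
#' @param geom_treated,geom_untreated [gradient_geometry()] per gradient;
#'   `geom_untreated` defaults to `geom_treated`.
#' @param calib_treated,calib_untreated [fit_ribosome_calibration()] per
#'   gradient; `calib_untreated` defaults to `calib_treated`.
#' @return A list with `log2_change`, and per-condition `position` and
#'   `avg_ribosomes`.
#' @export
oracle_translation_change <- function(treated, untreated, scheme,
                                      geom_treated,
                                      calib_treated,
                                      geom_untreated = geom_treated,
                                      calib_untreated = calib_treated) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  if (nrow(treated) != nrow(untreated)) {
    abort("treated and untreated profiles must have the same fraction count")
  }
  one <- function(profile, geom, calib) {
    ratio <- explicit_encode(profile, scheme)
    pos <- ratio_to_position(log2(ratio), scheme, method = "regression")
    t <- position_to_time(pos$position, geom)
    list(position = pos$position, k = time_to_ribosomes(calib, t))
  }
  tr <- one(treated, geom_treated, calib_treated)
  un <- one(untreated, geom_untreated, calib_untreated)
  list(
    log2_change = log2(tr$k / un$k),
    position_treated = tr$position,
    position_untreated = un$position,
    avg_ribosomes_treated = tr$k,
    avg_ribosomes_untreated = un$k
  )
}
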