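#' Array feature table columns
#'
#' Two-color array feature tables are tibbles with one row per array element:
#' `feature_id`, `gene_id`, `transcript_id`, `cy5`, `cy3` (channel
#' intensities), `log2_ratio` (log2(cy5/cy3)), `pixel_r` (pixel-level
#' Cy5-vs-Cy3 regression correlation), `ib_cy5`, `ib_cy3`
#' (intensity/background per channel), `is_control` (doping-control flag) and
#' `control_fraction` (assigned fraction for controls, NA otherwise).
#'
#' @param path Tab-delimited file with the required header.
#' @return A validated tibble.
#' @export
read_array_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  validate_array_table(df)
  df
}

#' @rdname read_array_table
#' @param table An array feature tibble.
#' @export
write_array_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

array_table_columns <- c(
  "feature_id", "gene_id", "transcript_id", "cy5", "cy3", "log2_ratio",
  "pixel_r", "ib_cy5", "ib_cy3", "is_control", "control_fraction"
)

validate_array_table <- function(table, need = array_table_columns) {
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    abort(paste0("array table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(table$feature_id)) {
    abort("`feature_id` must be unique within an array")
  }
  invisible(table)
}

#' Quality-filter array features
#'
#' Keeps features with a pixel-level Cy5-vs-Cy3 regression correlation of at
#' least `min_pixel_r` (default 0.6) OR an intensity/background ratio of at
#' least `min_ib` (default 2.5) in at least one channel. Both thresholds are
#' inclusive. Every dropped row is recorded with its reason.
#'
#' @param table An array feature tibble (see [read_array_table()]).
#' @param min_pixel_r Minimum pixel regression correlation. Default 0.6.
#' @param min_ib Minimum intensity/background ratio in the better channel.
#'   Default 2.5.
#' @return A list with elements `kept` (rows passing) and `rejected` (rows
#'   failing, with a `reason` column). `kept` and `rejected` partition the
#'   input exactly.
#' @export
quality_filter <- function(table, min_pixel_r = 0.6, min_ib = 2.5) {
  for (col in c("pixel_r", "ib_cy5", "ib_cy3")) {
    if (!col %in% names(table)) {
      abort(paste0("quality field `", col, "` is missing"))
    }
    if (anyNA(table[[col]])) {
      abort(paste0("quality field `", col, "` contains missing values"))
    }
  }
  pass_r <- table$pixel_r >= min_pixel_r
  pass_ib <- pmax(table$ib_cy5, table$ib_cy3) >= min_ib
  keep <- pass_r | pass_ib
  rejected <- table[!keep, , drop = FALSE]
  rejected$reason <- paste0(
    "pixel_r < ", min_pixel_r, " and max intensity/background < ", min_ib
  )
  list(kept = table[keep, , drop = FALSE], rejected = as_tibble(rejected))
}

#' Fit the dye-ratio calibration from doping controls
#'
#' Least-squares fit of measured control log2 ratios against the expected
#' per-fraction log2 ratios of the encoding scheme:
#' measured = slope * expected + intercept. The inverse affine map
#' (measured - intercept) / slope is applied downstream to put measured gene
#' ratios on the expected-ratio scale.
#'
#' @param controls Control rows of an array feature table (must have
#'   `log2_ratio` and `control_fraction`).
#' @param scheme The [encoding_scheme()] supplying expected per-fraction
#'   ratios.
#' @return An object of class `dye_calibration` with `slope`, `intercept`,
#'   `r_squared` and `n_controls`.
#' @export
fit_dye_calibration <- function(controls, scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  if (nrow(controls) == 0) abort("no control rows supplied")
  fr <- controls$control_fraction
  if (anyNA(fr)) abort("control rows must carry `control_fraction`")
  if (length(unique(fr)) < 2) {
    abort("controls from at least two distinct fractions are required")
  }
  expected <- scheme$expected_log2_ratio[fr]
  fit <- lm(controls$log2_ratio ~ expected)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("dye calibration slope must be positive")
  }
  ss_tot <- sum((controls$log2_ratio - mean(controls$log2_ratio))^2)
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1,
      n_controls = nrow(controls)
    ),
    class = "dye_calibration"
  )
}

#' @export
print.dye_calibration <- function(x, ...) {
  cat("<dye_calibration> measured = ", format(x$slope, digits = 4),
      " * expected + ", format(x$intercept, digits = 4), " (r^2 = ",
      format(x$r_squared, digits = 3), ", n = ", x$n_controls, ")\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_dye_calibration
#' @param x A `dye_calibration`.
#' @param ... Unused.
#' @export
tidy.dye_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_dye_calibration
#' @export
glance.dye_calibration <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_controls = x$n_controls)
}

#' Apply the inverse dye calibration to measured log2 ratios
#'
#' @param calib A [fit_dye_calibration()] result.
#' @param log2_ratio Measured log2 ratios.
#' @return Calibrated log2 ratios on the expected-ratio scale.
#' @export
apply_dye_calibration <- function(calib, log2_ratio) {
  stopifnot(inherits(calib, "dye_calibration"))
  (log2_ratio - calib$intercept) / calib$slope
}

#' Convert calibrated log2 ratios to fractional gradient positions
#'
#' Inverts the scheme's fraction-to-expected-ratio map. `"piecewise"` uses
#' linear interpolation between the integer-fraction expected ratios;
#' `"regression"` uses the line fit of expected ratio on fraction number (the
#' form used in the explicit qRT-PCR calculation). For the default log2-linear
#' ramp the two coincide exactly. Ratios outside the scheme's range clamp to
#' 1 or `n_fractions` with a flag; the unclamped value is retained.
#'
#' @param log2_ratio Calibrated log2 ratio(s).
#' @param scheme An [encoding_scheme()].
#' @param method `"piecewise"` (default) or `"regression"`.
#' @return A tibble with columns `position` (clamped to
#'   `[1, n_fractions]`), `position_unclamped` and `clamped`.
#' @export
ratio_to_position <- function(log2_ratio, scheme,
                              method = c("piecewise", "regression")) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  method <- match.arg(method)
  f <- seq_len(scheme$n_fractions)
  y <- scheme$expected_log2_ratio
  if (method == "piecewise") {
    pos <- interp_linear(y, f, log2_ratio)
  } else {
    fit <- lm(y ~ f)
    pos <- (log2_ratio - coef(fit)[1]) / coef(fit)[2]
  }
  clamped_pos <- pmin(pmax(pos, 1), scheme$n_fractions)
  tibble(
    position = unname(clamped_pos),
    position_unclamped = unname(pos),
    clamped = pos < 1 | pos > scheme$n_fractions
  )
}

#' Decode one encoded array into average ribosome numbers
#'
#' Full per-feature decode of a quality-filtered Gradient Encoding array
#' (one array = one replicate of one condition): the dye calibration is fit
#' from the array's own doping-control features, every non-control feature's
#' ratio is calibrated, inverted to a fractional gradient position, converted
#' to an elution time by linear interpolation between fraction midpoints, and
#' mapped to an average ribosome number with the gradient's ribosome
#' calibration.
#'
#' @param table A quality-filtered array feature tibble containing both
#'   control and non-control rows.
#' @param scheme The [encoding_scheme()] used for pooling.
#' @param geom The [gradient_geometry()] of this gradient.
#' @param ribo_calib The [fit_ribosome_calibration()] for this gradient.
#' @param dye_calib Optional pre-fit [fit_dye_calibration()]; fit from the
#'   table's control rows when `NULL`.
#' @return A tibble with one row per non-control feature: identifiers, the
#'   measured and calibrated log2 ratios, decoded `position` (clamped),
#'   `position_unclamped`, `clamped` flag, interpolated `time_s` and
#'   `avg_ribosomes`; `replicate` and `condition` columns pass through when
#'   present.
#' @export
decode_experiment <- function(table, scheme, geom, ribo_calib,
                              dye_calib = NULL) {
  stopifnot(inherits(scheme, "encoding_scheme"),
            inherits(geom, "gradient_geometry"),
            inherits(ribo_calib, "ribosome_calibration"))
  validate_array_table(
    table,
    need = c("feature_id", "gene_id", "transcript_id", "log2_ratio",
             "is_control", "control_fraction")
  )
  if (is.null(dye_calib)) {
    controls <- dplyr::filter(table, .data$is_control)
    if (nrow(controls) == 0) {
      abort("no doping-control rows present and no `dye_calib` supplied")
    }
    dye_calib <- fit_dye_calibration(controls, scheme)
  }
  features <- dplyr::filter(table, !.data$is_control)
  calibrated <- apply_dye_calibration(dye_calib, features$log2_ratio)
  pos <- ratio_to_position(calibrated, scheme)
  time_s <- position_to_time(pos$position, geom)
  out <- tibble(
    feature_id = features$feature_id,
    gene_id = features$gene_id,
    transcript_id = features$transcript_id,
    log2_ratio = features$log2_ratio,
    calibrated_log2_ratio = calibrated,
    position = pos$position,
    position_unclamped = pos$position_unclamped,
    clamped = pos$clamped,
    time_s = time_s,
    avg_ribosomes = time_to_ribosomes(ribo_calib, time_s)
  )
  for (col in c("replicate", "condition")) {
    if (col %in% names(features)) out[[col]] <- features[[col]]
  }
  out
}

#' Normalize an mRNA abundance array against spike-in controls
#'
#' For abundance arrays (sample vs reference), the measured red/green ratios
#' are normalized by linear regression to the known concentration ratios of a
#' set of spike-in controls doped into both samples: the affine fit of
#' measured on expected spike-in log2 ratios is inverted and applied to all
#' gene features, so spike-ins doped 1:1 map to 0 after correction. Gene-level
#' values are the mean of corrected feature ratios per gene.
#'
#' @param table An array feature tibble; spike-in rows flagged `is_control`.
#' @param spike_ratios A tibble mapping spike-ins to known log2 concentration
#'   ratios, columns `feature_id` and `expected_log2_ratio`; at least two
#'   distinct expected levels must be represented.
#' @return A list with `genes` (tibble: `gene_id`, `log2_abundance_ratio`,
#'   `n_features`) and `calibration` (the spike-in fit: slope, intercept).
#' @export
normalize_abundance <- function(table, spike_ratios) {
  validate_array_table(
    table,
    need = c("feature_id", "gene_id", "log2_ratio", "is_control")
  )
  spikes <- dplyr::inner_join(
    dplyr::filter(table, .data$is_control),
    spike_ratios,
    by = "feature_id"
  )
  if (length(unique(spikes$expected_log2_ratio)) < 2) {
    abort("need spike-ins at two or more distinct known ratios")
  }
  fit <- lm(spikes$log2_ratio ~ spikes$expected_log2_ratio)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    abort("spike-in calibration slope must be positive")
  }
  genes <- table |>
    dplyr::filter(!.data$is_control) |>
    dplyr::mutate(corrected = (.data$log2_ratio - intercept) / slope) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      log2_abundance_ratio = mean(.data$corrected),
      n_features = dplyr::n(),
      .groups = "drop"
    )
  list(
    genes = genes,
    calibration = list(slope = slope, intercept = intercept)
  )
}
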