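#' Product predictor of protein production change
#'
#' The expected log2 change in protein production from independent changes in
#' translation and mRNA abundance is the log of their product, i.e. the sum
#' of the two log2 changes.
#'
#' @param dt,da Log2 change in translation and in mRNA abundance.
#' @return `dt + da`.
#' @export
product_predictor <- function(dt, da) {
  dt + da
}

#' Correlate genomic predictors with protein production changes
#'
#' For genes with translation, abundance and protein-production changes,
#' reports Spearman and Pearson correlations of the protein change against
#' (i) the translation change, (ii) the abundance change and (iii) their
#' product predictor, with pairwise-complete handling. Optionally excludes
#' translation-apparatus genes (ribosomal proteins, initiation and elongation
#' factors) first, reporting how many were removed.
#'
#' @param records Tibble with columns `gene_id`, `d_translation`,
#'   `d_abundance`, `d_protein` and (optionally) `apparatus` (logical flag).
#' @param exclude_apparatus Drop apparatus-flagged genes before correlating.
#' @return A list with `correlations` (tibble: `predictor`, `spearman`,
#'   `pearson`, `n`), `n_excluded` and `n_total`.
#' @export
correlation_report <- function(records, exclude_apparatus = FALSE) {
  n_total <- nrow(records)
  n_excluded <- 0L
  if (exclude_apparatus) {
    if (!"apparatus" %in% names(records)) {
      abort("`apparatus` column required when `exclude_apparatus = TRUE`")
    }
    n_excluded <- sum(records$apparatus, na.rm = TRUE)
    records <- dplyr::filter(records, !.data$apparatus)
  }
  predictors <- list(
    translation = records$d_translation,
    abundance = records$d_abundance,
    product = product_predictor(records$d_translation, records$d_abundance)
  )
  rows <- purrr::imap(predictors, function(x, name) {
    ok <- is.finite(x) & is.finite(records$d_protein)
    if (sum(ok) < 3) {
      abort(paste0("fewer than 3 complete records for predictor `", name, "`"))
    }
    tibble(
      predictor = name,
      spearman = cor(x[ok], records$d_protein[ok], method = "spearman"),
      pearson = cor(x[ok], records$d_protein[ok], method = "pearson"),
      n = sum(ok)
    )
  })
  list(
    correlations = dplyr::bind_rows(rows),
    n_excluded = n_excluded,
    n_total = n_total
  )
}

#' Median/SD normalization of per-gene changes
#'
#' Subtracts the median and divides by the standard deviation, the scaling
#' used for cross-experiment heatmap display (median = 0, SD = 1).
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Normalized values with median exactly 0 and SD exactly 1.
#' @export
zscore_normalize <- function(values) {
  if (length(unique(values)) < 2) {
    abort("need at least two distinct values (zero SD)")
  }
  centered <- values - median(values)
  centered / sd(centered)
}
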