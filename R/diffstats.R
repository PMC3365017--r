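#' Mean-center array columns
#'
#' Subtracts each sample column's mean, removing per-array offsets before the
#' two-class statistic is computed. Idempotent.
#'
#' @param mat Numeric matrix, rows = genes/oligos, columns = samples.
#' @return The centered matrix.
#' @export
center_arrays <- function(mat) {
  sweep(mat, 2, colMeans(mat))
}

check_two_classes <- function(labels, class1, class2, n_col) {
  if (length(labels) != n_col) {
    abort("`labels` must have one entry per matrix column")
  }
  n1 <- sum(labels == class1)
  n2 <- sum(labels == class2)
  if (n1 + n2 != length(labels)) {
    abort(paste0("labels must all be `", class1, "` or `", class2, "`"))
  }
  if (n1 < 2 || n2 < 2) abort("need at least two samples per class")
  list(i1 = which(labels == class1), i2 = which(labels == class2))
}

# moderated two-class statistic and its ingredients for a (possibly
# relabeled) column split
d_components <- function(mat, i1, i2) {
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m2 - m1, s = s)
}

# d = diff / (s + s0), with 0/0 (no change, no variance) defined as 0
safe_d <- function(comp, s0) {
  denom <- comp$s + s0
  ifelse(comp$diff == 0 & denom == 0, 0, comp$diff / denom)
}

#' SAM-style moderated two-class statistic
#'
#' For each row, d = (mean(class2) - mean(class1)) / (s + s0), where s is the
#' unpaired pooled standard error and s0 is a fudge factor guarding against
#' rows with tiny variance. Sample columns are mean-centered first.
#'
#' @param mat Numeric matrix, rows = genes/oligos, columns = samples (log2
#'   values).
#' @param labels Character/factor of length `ncol(mat)` giving each column's
#'   class.
#' @param s0 Fudge factor; `"auto"` (default) uses the median of s over rows.
#' @param class1,class2 Label values for the reference (untreated) and
#'   comparison (treated) class; d is class2 minus class1.
#' @param center Mean-center columns first (default TRUE).
#' @return Numeric vector of d statistics, one per row, with the s values and
#'   s0 attached as attributes `s` and `s0`.
#' @export
sam_statistic <- function(mat, labels, s0 = "auto",
                          class1 = "untreated", class2 = "treated",
                          center = TRUE) {
  mat <- as.matrix(mat)
  idx <- check_two_classes(labels, class1, class2, ncol(mat))
  if (center) mat <- center_arrays(mat)
  comp <- d_components(mat, idx$i1, idx$i2)
  if (identical(s0, "auto")) s0 <- median(comp$s)
  d <- safe_d(comp, s0)
  attr(d, "s") <- comp$s
  attr(d, "s0") <- s0
  d
}

# all (or sampled) assignments of columns into a class-1 set of size n1;
# returns a list of index vectors. "all" enumerates choose(n, n1) splits,
# including the observed one.
permutation_splits <- function(n, n1, n_permutations, seed = NULL) {
  if (identical(n_permutations, "all")) {
    splits <- utils::combn(n, n1, simplify = FALSE)
  } else {
    if (!is.numeric(n_permutations) || n_permutations < 2) {
      abort("`n_permutations` must be \"all\" or a number >= 2")
    }
    if (!is.null(seed)) set.seed(seed)
    splits <- replicate(n_permutations, sort(sample.int(n, n1)),
                        simplify = FALSE)
  }
  splits
}

#' Permutation-based false discovery rates for the SAM statistic
#'
#' Builds the null distribution of d by relabeling sample columns. With
#' `n_permutations = "all"` every distinct assignment of columns to classes is
#' enumerated (20 splits for 3 vs 3), removing any seed dependence. For each
#' candidate |d| threshold, FDR = pi0 x median permuted false-call count /
#' observed call count, where pi0 is estimated from the proportion of observed
#' d values inside the interquartile range of the permuted d values. Each
#' row's q-value is the minimum FDR over thresholds that call it; q-values are
#' therefore nonincreasing in |d| and are reported in percent, clipped to
#' [0, 100].
#'
#' @inheritParams sam_statistic
#' @param n_permutations `"all"` (default) or a number of random relabelings
#'   (>= 2).
#' @param seed Seed for random relabelings; ignored when exhaustive.
#' @return A tibble with one row per matrix row: `mean_change` (class2 minus
#'   class1 of column-centered values), `d`, `q_percent`.
#' @export
sam_fdr <- function(mat, labels, n_permutations = "all", seed = NULL,
                    s0 = "auto", class1 = "untreated", class2 = "treated") {
  mat <- as.matrix(mat)
  idx <- check_two_classes(labels, class1, class2, ncol(mat))
  cmat <- center_arrays(mat)
  obs <- d_components(cmat, idx$i1, idx$i2)
  if (identical(s0, "auto")) s0 <- median(obs$s)
  d_obs <- safe_d(obs, s0)

  n1 <- length(idx$i1)
  splits <- permutation_splits(ncol(mat), n1, n_permutations, seed)
  d_perm <- vapply(splits, function(i1) {
    comp <- d_components(cmat, i1, setdiff(seq_len(ncol(mat)), i1))
    safe_d(comp, s0)
  }, numeric(nrow(mat)))

  qv <- sam_qvalues(d_obs, d_perm)
  tibble(mean_change = obs$diff, d = unname(d_obs), q_percent = qv)
}

# tail-area q-values from observed and permuted d
sam_qvalues <- function(d_obs, d_perm) {
  iqr <- quantile(d_perm, c(0.25, 0.75))
  pi0 <- min(1, sum(d_obs >= iqr[1] & d_obs <= iqr[2]) /
                  (0.5 * length(d_obs)))
  abs_obs <- abs(d_obs)
  thresholds <- sort(unique(abs_obs))
  sorted_obs <- sort(abs_obs)
  # exact counts of |d| >= t via the count of values strictly below t
  n_called <- length(abs_obs) -
    findInterval(thresholds, sorted_obs, left.open = TRUE)
  false_counts <- vapply(seq_len(ncol(d_perm)), function(b) {
    sc <- sort(abs(d_perm[, b]))
    length(sc) - findInterval(thresholds, sc, left.open = TRUE)
  }, numeric(length(thresholds)))
  false_counts <- matrix(false_counts, nrow = length(thresholds))
  med_false <- apply(false_counts, 1, median)
  fdr <- pmin(100, pmax(0, 100 * pi0 * med_false / pmax(n_called, 1)))
  # q for a row = min FDR over thresholds at or below its |d|
  running_min <- cummin(fdr)
  unname(running_min[match(abs_obs, thresholds)])
}

#' Two-class differential test with permutation FDR
#'
#' Tidy wrapper around [sam_statistic()] and [sam_fdr()] for long-format
#' data: one row per (id, sample) measurement.
#'
#' @param data A data frame with one measurement per row.
#' @param id,value,condition,replicate Column names (strings) holding the
#'   row identifier, the log2 measurement, the condition label and the
#'   replicate index.
#' @param fdr_cutoff Significance cutoff in percent (default 10).
#' @inheritParams sam_fdr
#' @return A tibble with `gene_id` (from `id`), `mean_change`, `d`,
#'   `q_percent`, `significant` and `direction` ("up", "down").
#' @export
sam_test <- function(data, id = "gene_id", value = "value",
                     condition = "condition", replicate = "replicate",
                     fdr_cutoff = 10, n_permutations = "all", seed = NULL,
                     s0 = "auto", class1 = "untreated", class2 = "treated") {
  wide <- data |>
    dplyr::select(dplyr::all_of(c(id, value, condition, replicate))) |>
    tidyr::pivot_wider(
      names_from = dplyr::all_of(c(condition, replicate)),
      values_from = dplyr::all_of(value),
      names_sep = "."
    )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(mat)) {
    keep <- stats::complete.cases(mat)
    mat <- mat[keep, , drop = FALSE]
    wide <- wide[keep, , drop = FALSE]
  }
  labels <- sub("\\..*$", "", colnames(mat))
  res <- sam_fdr(mat, labels, n_permutations = n_permutations, seed = seed,
                 s0 = s0, class1 = class1, class2 = class2)
  tibble(
    gene_id = wide[[1]],
    mean_change = res$mean_change,
    d = res$d,
    q_percent = res$q_percent,
    significant = res$q_percent <= fdr_cutoff,
    direction = ifelse(res$d >= 0, "up", "down")
  )
}

#' Collapse multi-oligo values to gene level
#'
#' Genes represented by several array oligos are collapsed either by
#' averaging the oligo values (`"mean"`) or by taking the value of the oligo
#' with the largest absolute change (`"max_change"`), optionally judged on a
#' separate selector column (e.g. pick the oligo by its translation change
#' while collapsing another quantity).
#'
#' @param values Tibble with columns `oligo_id` and `value` (and optionally
#'   `selector` used for `"max_change"`; defaults to `value`).
#' @param mapping Tibble with columns `oligo_id` and `gene_id`; every oligo in
#'   `values` must be mapped exactly once.
#' @param mode `"mean"` or `"max_change"`.
#' @return A tibble with `gene_id`, `value` and `n_oligos`.
#' @export
collapse_oligos <- function(values, mapping, mode = c("mean", "max_change")) {
  mode <- match.arg(mode)
  unmapped <- setdiff(values$oligo_id, mapping$oligo_id)
  if (length(unmapped) > 0) {
    abort(paste0("unmapped oligo(s): ", paste(unmapped, collapse = ", ")))
  }
  if (anyDuplicated(mapping$oligo_id)) {
    abort("each oligo must map to exactly one gene")
  }
  joined <- dplyr::inner_join(values, mapping, by = "oligo_id")
  if (!"selector" %in% names(joined)) joined$selector <- joined$value
  joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      value = if (mode == "mean") mean(.data$value) else
        .data$value[which.max(abs(.data$selector))],
      n_oligos = dplyr::n(),
      .groups = "drop"
    )
}

#' Classify genes by mode of regulation
#'
#' Crosses translational significance with the size of the mRNA abundance
#' change: a gene is `translation_only` when it is significant in the
#' translation test and its abundance change lies within `sd_multiple`
#' standard deviations of the mean abundance change over all detectable genes
#' (mean and SD computed over every gene supplied, not only significant
#' ones).
#'
#' @param diff_translation Tibble with columns `gene_id` and `significant`
#'   (e.g. from [sam_test()]).
#' @param abundance_changes Tibble with columns `gene_id` and `log2_change`
#'   covering the same gene set.
#' @param sd_multiple Width of the "unchanged abundance" band in SDs
#'   (default 1).
#' @return A tibble with `gene_id`, `abundance_z` and `class` in
#'   `{"translation_only", "both", "abundance_only", "neither"}`.
#' @export
classify_translation_only <- function(diff_translation, abundance_changes,
                                      sd_multiple = 1) {
  if (!setequal(diff_translation$gene_id, abundance_changes$gene_id)) {
    abort("translation and abundance tables must cover the same gene set")
  }
  merged <- dplyr::inner_join(
    dplyr::select(diff_translation, "gene_id", "significant"),
    dplyr::select(abundance_changes, "gene_id", "log2_change"),
    by = "gene_id"
  )
  mu <- mean(merged$log2_change)
  sigma <- sd(merged$log2_change)
  if (!is.finite(sigma) || sigma == 0) {
    abort("abundance changes have zero spread; z-scores undefined")
  }
  z <- (merged$log2_change - mu) / sigma
  within <- abs(z) <= sd_multiple
  tibble(
    gene_id = merged$gene_id,
    abundance_z = z,
    class = dplyr::case_when(
      merged$significant & within ~ "translation_only",
      merged$significant & !within ~ "both",
      !merged$significant & !within ~ "abundance_only",
      TRUE ~ "neither"
    )
  )
}
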