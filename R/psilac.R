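#' Read a pulsed-SILAC peptide ratio table
#'
#' Tab-delimited with columns `peptide`, `protein`, `gene`, `unique`
#' (logical: peptide sequence unique to the protein), `prob` (identification
#' probability), `ratio_mh` (medium/heavy isotope ratio, > 0), `quality_ok`
#' (quantitation passed curation) and `direction` (`"forward"` or
#' `"reverse"`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_peptide_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("peptide", "protein", "gene", "unique", "prob", "ratio_mh",
            "quality_ok", "direction")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("peptide table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Filter and median-center a peptide ratio table
#'
#' Keeps peptides with identification probability >= `min_prob` (default
#' 0.95) whose quantitative ratio passed curation (`quality_ok`), then
#' median-centers the log2 ratios to zero within each direction to remove
#' sample-loading bias. Rejected rows are returned with reasons.
#'
#' @param table A peptide ratio tibble (see [read_peptide_table()]).
#' @param min_prob Identification probability threshold, inclusive.
#' @return A list with `kept` (filtered table with an added `log2_ratio`
#'   column, median-centered per direction) and `rejected` (rows dropped, with
#'   `reason`).
#' @export
filter_peptide_table <- function(table, min_prob = 0.95) {
  if (any(table$ratio_mh <= 0)) abort("peptide ratios must be positive")
  keep <- table$prob >= min_prob & table$quality_ok
  rejected <- table[!keep, , drop = FALSE]
  rejected$reason <- dplyr::case_when(
    rejected$prob < min_prob & !rejected$quality_ok ~
      "identification probability and quantitation quality",
    rejected$prob < min_prob ~ paste0("identification probability < ", min_prob),
    TRUE ~ "quantitation flagged low quality"
  )
  kept <- table[keep, , drop = FALSE]
  if (nrow(kept) == 0) abort("no peptides remain after filtering")
  kept <- kept |>
    dplyr::mutate(log2_ratio = log2(.data$ratio_mh)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(log2_ratio = .data$log2_ratio - median(.data$log2_ratio)) |>
    dplyr::ungroup()
  list(kept = kept, rejected = as_tibble(rejected))
}

#' Aggregate peptide ratios to protein log ratios
#'
#' Per protein, the geometric mean of the assigned peptide ratios (the
#' arithmetic mean of their log2 ratios), restricted to proteins identified by
#' at least `min_unique_peptides` unique peptide sequences.
#'
#' @param filtered The `kept` table from [filter_peptide_table()].
#' @param direction Optional: restrict to one experiment direction.
#' @param min_unique_peptides Minimum distinct unique-peptide sequences per
#'   protein (default 2).
#' @return A tibble with `protein`, `gene`, `log2_ratio` (geometric-mean log2
#'   medium/heavy in the table's native orientation), `n_peptides` and
#'   `n_unique_peptides`.
#' @export
protein_log_ratios <- function(filtered, direction = NULL,
                               min_unique_peptides = 2) {
  tbl <- filtered
  if (!is.null(direction)) {
    tbl <- dplyr::filter(tbl, .data$direction == !!direction)
  }
  if (!"log2_ratio" %in% names(tbl)) tbl$log2_ratio <- log2(tbl$ratio_mh)
  tbl |>
    dplyr::group_by(.data$protein, .data$gene) |>
    dplyr::summarise(
      log2_ratio = mean(.data$log2_ratio),
      n_peptides = dplyr::n(),
      n_unique_peptides = length(unique(.data$peptide[.data$unique])),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_unique_peptides >= min_unique_peptides)
}

#' Combine forward and reverse pSILAC experiments
#'
#' The forward experiment stores medium/heavy = treated/untreated; the
#' reverse (label-swap) experiment stores untreated/treated. Reverse log2
#' ratios are negated so both report treated:untreated, then per-protein
#' values are combined as the mean of the available log2 values (the
#' geometric mean on the ratio scale). Proteins seen in only one direction
#' keep that value and are flagged.
#'
#' @param forward,reverse [protein_log_ratios()] tables in their native
#'   orientation.
#' @return A tibble with `protein`, `gene`, `log2_ratio`
#'   (treated/untreated), `n_unique_peptides` (maximum over directions) and
#'   `single_direction`.
#' @export
combine_forward_reverse <- function(forward, reverse) {
  fwd <- dplyr::select(forward, "protein", "gene",
                       fwd_log2 = "log2_ratio",
                       fwd_unique = "n_unique_peptides")
  rev <- dplyr::select(reverse, "protein", "gene",
                       rev_log2 = "log2_ratio",
                       rev_unique = "n_unique_peptides")
  merged <- dplyr::full_join(fwd, rev, by = c("protein", "gene"))
  flipped <- -merged$rev_log2
  both <- !is.na(merged$fwd_log2) & !is.na(flipped)
  log2_ratio <- dplyr::coalesce(merged$fwd_log2, flipped)
  log2_ratio[both] <- (merged$fwd_log2[both] + flipped[both]) / 2
  tibble(
    protein = merged$protein,
    gene = merged$gene,
    log2_ratio = log2_ratio,
    n_unique_peptides = pmax(merged$fwd_unique, merged$rev_unique,
                             na.rm = TRUE),
    single_direction = !both
  )
}
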