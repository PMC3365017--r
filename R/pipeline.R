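#' Decode one simulated gradient run
#'
#' Quality-filters the run's array features and decodes them to average
#' ribosome numbers. By default the run's own peak calibration is used
#' (isolating the decode from peak detection); with `use_trace = TRUE` the
#' calibration is re-derived from the A260 trace via [find_peaks()] and
#' [fit_ribosome_calibration()], as one would with real data (peak times are
#' then quantized to the trace sampling step).
#'
#' @param run A [simulate_gradient_run()] result.
#' @param scheme The cohort [encoding_scheme()].
#' @param use_trace Re-derive the ribosome calibration from the trace.
#' @param min_prominence,search_window Peak-finder settings when
#'   `use_trace = TRUE`.
#' @return The [decode_experiment()] tibble for this run.
#' @export
decode_run <- function(run, scheme, use_trace = FALSE,
                       min_prominence = 0.05, search_window = NULL) {
  calib <- run$calibration
  if (use_trace) {
    if (is.null(search_window)) {
      search_window <- c(75, max(run$trace$time_s))
    }
    peaks <- find_peaks(run$trace, min_prominence, search_window)
    calib <- fit_ribosome_calibration(peaks)
  }
  filtered <- quality_filter(run$features)
  decode_experiment(filtered$kept, scheme, run$geometry, calib)
}

#' Decode every gradient run of a simulated experiment
#'
#' Decodes all runs and keeps only non-control features that passed quality
#' filtering in every replicate of both conditions and decoded to a positive
#' average ribosome number throughout, so every retained feature has a
#' complete log2 profile across samples.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param use_trace Passed to [decode_run()].
#' @return A tibble with one row per (feature, replicate, condition):
#'   identifiers, `position`, `avg_ribosomes` and `log2_load`.
#' @export
decode_cohort <- function(experiment, use_trace = FALSE) {
  decoded <- purrr::map_dfr(experiment$runs, decode_run,
                            scheme = experiment$scheme,
                            use_trace = use_trace)
  n_runs <- length(experiment$runs)
  decoded |>
    dplyr::mutate(log2_load = ifelse(.data$avg_ribosomes > 0,
                                     log2(.data$avg_ribosomes), NA_real_)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::filter(dplyr::n() == n_runs, !anyNA(.data$log2_load)) |>
    dplyr::ungroup()
}

#' Gene-level differential translation table
#'
#' Runs the permutation test on per-oligo log2 average ribosome numbers and
#' collapses to genes: the gene change is the mean of its oligo changes, and
#' a gene is significant when any of its oligos passes the FDR cutoff.
#'
#' @param decoded A [decode_cohort()] tibble.
#' @param fdr_cutoff Percent FDR cutoff (default 10).
#' @param ... Passed to [sam_test()].
#' @return A tibble with `gene_id`, `mean_change`, `d` (largest-|d| oligo),
#'   `q_percent` (minimum over oligos), `n_oligos` and `significant`.
#' @export
diff_translation <- function(decoded, fdr_cutoff = 10, ...) {
  per_oligo <- sam_test(
    dplyr::rename(decoded, oligo_id = "feature_id"),
    id = "oligo_id", value = "log2_load", fdr_cutoff = fdr_cutoff, ...
  ) |>
    dplyr::rename(oligo_id = "gene_id")
  mapping <- dplyr::distinct(decoded, oligo_id = .data$feature_id,
                             .data$gene_id)
  dplyr::inner_join(per_oligo, mapping, by = "oligo_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      mean_change = mean(.data$mean_change),
      d = .data$d[which.max(abs(.data$d))],
      q_percent = min(.data$q_percent),
      n_oligos = dplyr::n(),
      significant = any(.data$significant),
      .groups = "drop"
    )
}

#' Gene-level mRNA abundance changes from simulated abundance arrays
#'
#' Normalizes each abundance array against its spike-ins, then averages the
#' per-replicate treated-minus-untreated differences.
#'
#' @param experiment A [simulate_experiment()] result.
#' @return A list with `per_sample` (gene x sample normalized ratios) and
#'   `changes` (tibble: `gene_id`, `log2_change`).
#' @export
abundance_changes <- function(experiment) {
  per_sample <- purrr::map_dfr(experiment$abundance_runs, function(run) {
    norm <- normalize_abundance(run$features, run$spike_ratios)
    norm$genes |>
      dplyr::mutate(replicate = run$features$replicate[1],
                    condition = run$features$condition[1])
  })
  changes <- per_sample |>
    dplyr::select("gene_id", "replicate", "condition",
                  "log2_abundance_ratio") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "log2_abundance_ratio") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(log2_change = mean(.data$treated - .data$untreated),
                     .groups = "drop")
  list(per_sample = per_sample, changes = changes)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Decode, differential translation, abundance normalization,
#' translation-only classification, pSILAC aggregation and the integrated
#' correlation report, end to end.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param fdr_cutoff Percent FDR cutoff for the translation test.
#' @param use_trace Re-derive peak calibrations from the A260 traces.
#' @return A list with `decoded`, `translation`, `abundance`,
#'   `classification`, `proteins`, `records` (merged per-gene change table)
#'   and `correlations`.
#' @export
run_pipeline <- function(experiment, fdr_cutoff = 10, use_trace = FALSE) {
  decoded <- decode_cohort(experiment, use_trace = use_trace)
  translation <- diff_translation(decoded, fdr_cutoff = fdr_cutoff)
  abundance <- abundance_changes(experiment)

  shared <- intersect(translation$gene_id, abundance$changes$gene_id)
  classification <- classify_translation_only(
    dplyr::filter(translation, .data$gene_id %in% shared),
    dplyr::filter(abundance$changes, .data$gene_id %in% shared)
  )

  filtered <- filter_peptide_table(experiment$psilac$peptides)
  fwd <- protein_log_ratios(filtered$kept, direction = "forward")
  rev <- protein_log_ratios(filtered$kept, direction = "reverse")
  proteins <- combine_forward_reverse(fwd, rev)

  records <- translation |>
    dplyr::select("gene_id", d_translation = "mean_change") |>
    dplyr::inner_join(
      dplyr::select(abundance$changes, "gene_id", d_abundance = "log2_change"),
      by = "gene_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(proteins, gene_id = "gene", d_protein = "log2_ratio"),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      dplyr::select(experiment$truth, "gene_id", "apparatus"),
      by = "gene_id"
    )

  list(
    decoded = decoded,
    translation = translation,
    abundance = abundance$changes,
    classification = classification,
    proteins = proteins,
    records = records,
    correlations = correlation_report(records)$correlations
  )
}

#' Compare the qRT-PCR encoding oracle with the array decode per panel gene
#'
#' For every gene in the simulated qRT-PCR validation panel, computes the
#' translation change twice: once through the explicit per-fraction encoding
#' oracle on the qPCR profiles, and once through the array decode (averaging
#' oligos within each array), using one replicate's treated and untreated
#' gradients with their own calibrations.
#'
#' The decode side averages each panel gene's linear average ribosome number
#' over its oligos and all replicate arrays of a condition before taking the
#' log ratio, as one would when summarizing replicate experiments.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param replicate Which replicate's gradients carry the qPCR profiles
#'   (default 1).
#' @return A tibble with `gene_id`, `oracle_change` and `decoded_change`
#'   (both log2 treated/untreated average ribosome number).
#' @export
validate_oracle_panel <- function(experiment, replicate = 1) {
  run_u <- experiment$runs[[paste0("untreated_", replicate)]]
  run_t <- experiment$runs[[paste0("treated_", replicate)]]
  if (is.null(run_u) || is.null(run_t)) abort("replicate not simulated")
  scheme <- experiment$scheme
  decoded <- purrr::map_dfr(experiment$runs, decode_run, scheme = scheme)
  dec_u <- decoded[decoded$condition == "untreated", ]
  dec_t <- decoded[decoded$condition == "treated", ]
  panel <- experiment$truth$gene_id[experiment$truth$qpcr_panel]
  purrr::map_dfr(panel, function(g) {
    profile_of <- function(run) {
      q <- dplyr::filter(run$qpcr, .data$gene == g)
      normalize_qpcr_profile(
        dplyr::select(q, "fraction", "mean", "se"),
        dplyr::select(q, "fraction", mean = "control_mean",
                      se = "control_se")
      )
    }
    orc <- oracle_translation_change(
      profile_of(run_t), profile_of(run_u), scheme,
      geom_treated = run_t$geometry, calib_treated = run_t$calibration,
      geom_untreated = run_u$geometry, calib_untreated = run_u$calibration
    )
    k_u <- mean(dec_u$avg_ribosomes[dec_u$gene_id == g])
    k_t <- mean(dec_t$avg_ribosomes[dec_t$gene_id == g])
    tibble(
      gene_id = g,
      oracle_change = orc$log2_change,
      decoded_change = log2(k_t / k_u)
    )
  })
}
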