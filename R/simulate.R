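#' Configuration for a synthetic Gradient Encoding experiment
#'
#' Bundles every tunable of the synthetic generator: cohort size, gradient
#' geometry and true peak calibration, encoding ramp, per-class regulation
#' proportions and effect sizes, and all noise scales. Every stochastic
#' output is driven by the single `seed`, split into documented per-component
#' streams (see [sub_seed()]).
#'
#' @param seed Integer seed; mandatory.
#' @param n_genes Number of genes in the cohort. Default 2000.
#' @param n_fractions Number of gradient fractions. Default 15.
#' @param n_replicates Biological replicates per condition. Default 3.
#' @param a_min,a_max,ramp Encoding ramp endpoints and shape, see
#'   [encoding_scheme()].
#' @param total_time Gradient elution span in seconds, fractions equally
#'   spaced. Default 450.
#' @param alpha,beta True ribosome calibration k = alpha + beta * ln(t).
#'   Defaults place the monosome peak near 90 s and six peaks within the
#'   gradient.
#' @param n_peaks Number of resolvable ribosome peaks in the A260 trace.
#' @param peak_jitter_sd Per-replicate multiplicative jitter of peak times
#'   (SD of log). Default 0.01.
#' @param search_window Time window used to look for ribosome peaks
#'   (excludes 40S/60S subunit peaks near the top). Default c(75, total_time).
#' @param class_proportions Named proportions over regulation classes
#'   `null`, `translation_up`, `translation_down`, `abundance_up`,
#'   `abundance_down`, `coupled`; must sum to 1.
#' @param effect_range Range of absolute log2 effect sizes. Default
#'   c(0.7, 2).
#' @param abundance_effect_scale Abundance effects are drawn from
#'   `effect_range` and scaled by this factor, keeping the cohort's
#'   translation-effect variance dominant (as observed for this system).
#'   Default 0.7.
#' @param load_range Range (log-uniform) of untreated mean ribosome loads.
#'   Default c(1, 4.2).
#' @param load_clamp Admissible load range; treated loads are clamped here
#'   (a transcript cannot sediment past the gradient bottom) and the realized
#'   post-clamp change is recorded as truth. Default c(0.55, 5.8).
#' @param dispersion_range Range of per-gene gradient spread (SD in position
#'   units). Default c(0.6, 0.9).
#' @param abundance_sdlog SD of log baseline mRNA abundance. Default 1.
#' @param fraction_noise_sdlog Lognormal noise on per-fraction masses.
#'   Default 0.04.
#' @param array_log2_sd Gaussian noise on measured array log2 ratios.
#'   Default 0.06.
#' @param abundance_log2_sd Noise on abundance-array gene ratios.
#'   Default 0.15.
#' @param dye_slope_sd,dye_offset_sd Per-array dye distortion (slope around
#'   1, offset around 0) that the doping-control regression must undo.
#' @param quality_fail_rate Fraction of array features drawn to fail the
#'   quality filter. Default 0.05.
#' @param controls_per_fraction Doping controls per fraction. Default 4.
#' @param qpcr_genes Size of the qRT-PCR validation panel. Default 9.
#' @param qpcr_cv Coefficient of variation of triplicate qPCR means.
#'   Default 0.05.
#' @param n_oligo_probs Probabilities that a gene is represented by 1, 2 or 3
#'   array oligos.
#' @param psilac_genes Number of genes with pSILAC coverage. Default 250.
#' @param c_translation,c_abundance Coupling of protein production change to
#'   translation and abundance changes. Defaults 1 and 1.
#' @param protein_log2_sd Protein-level noise. Default 0.3.
#' @param peptides_range Range of peptides per protein per direction.
#'   Default c(1, 8).
#' @param peptide_log2_sd Per-peptide quantitation noise. Default 0.2.
#' @param prob_below_rate Fraction of peptides drawn with identification
#'   probability below 0.95. Default 0.05.
#' @param peptide_quality_fail_rate Fraction of peptides flagged low-quality
#'   by curation. Default 0.02.
#' @param apparatus_rate_down,apparatus_rate_other Probability that a
#'   translation-down gene / any other gene is a translation-apparatus gene.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       n_fractions = 15,
                       n_replicates = 3,
                       a_min = 0.1, a_max = 0.9, ramp = "log2",
                       total_time = 450,
                       alpha = -13.4, beta = 3.2, n_peaks = 6,
                       peak_jitter_sd = 0.01,
                       search_window = c(75, total_time),
                       class_proportions = c(
                         null = 0.925, translation_up = 0.02,
                         translation_down = 0.02, abundance_up = 0.0075,
                         abundance_down = 0.0075, coupled = 0.02
                       ),
                       effect_range = c(0.7, 2),
                       abundance_effect_scale = 0.7,
                       load_range = c(1, 4.2),
                       load_clamp = c(0.55, 5.8),
                       dispersion_range = c(0.6, 0.9),
                       abundance_sdlog = 1,
                       fraction_noise_sdlog = 0.04,
                       array_log2_sd = 0.06,
                       abundance_log2_sd = 0.15,
                       dye_slope_sd = 0.05,
                       dye_offset_sd = 0.1,
                       quality_fail_rate = 0.05,
                       controls_per_fraction = 4,
                       qpcr_genes = 9,
                       qpcr_cv = 0.05,
                       n_oligo_probs = c(0.70, 0.25, 0.05),
                       psilac_genes = 250,
                       c_translation = 1,
                       c_abundance = 1,
                       protein_log2_sd = 0.3,
                       peptides_range = c(1, 8),
                       peptide_log2_sd = 0.2,
                       prob_below_rate = 0.05,
                       peptide_quality_fail_rate = 0.02,
                       apparatus_rate_down = 0.15,
                       apparatus_rate_other = 0.01) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("`class_proportions` must sum to 1")
  }
  needed <- c("null", "translation_up", "translation_down", "abundance_up",
              "abundance_down", "coupled")
  if (!setequal(names(class_proportions), needed)) {
    abort("`class_proportions` must be named over the six regulation classes")
  }
  cfg <- as.list(environment())
  sds <- c("peak_jitter_sd", "fraction_noise_sdlog", "array_log2_sd",
           "abundance_log2_sd", "dye_slope_sd", "dye_offset_sd", "qpcr_cv",
           "protein_log2_sd", "peptide_log2_sd")
  if (any(unlist(cfg[sds]) < 0)) abort("noise scales must be nonnegative")
  structure(cfg, class = "sim_config")
}

#' Zero out every noise source of a configuration
#'
#' Convenience for round-trip checks: returns the configuration with all
#' noise scales, jitter, distortions and failure rates set to zero.
#'
#' @param config A [sim_config()].
#' @return The modified configuration.
#' @export
noiseless <- function(config) {
  for (f in c("peak_jitter_sd", "fraction_noise_sdlog", "array_log2_sd",
              "abundance_log2_sd", "dye_slope_sd", "dye_offset_sd",
              "qpcr_cv", "protein_log2_sd", "peptide_log2_sd",
              "quality_fail_rate", "prob_below_rate",
              "peptide_quality_fail_rate")) {
    config[[f]] <- 0
  }
  config
}

#' Derive a component sub-seed from the master seed
#'
#' All randomness flows from the configuration's single seed through
#' deterministic per-component streams: stream 1 is the truth draw, streams
#' 100 + 10 * replicate + (condition == "treated") are the gradient runs,
#' 300 + the same offset the abundance arrays, and 500 the pSILAC draw.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream index.
#' @return An integer seed below 2^31.
#' @export
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% 2147483629)
}

run_stream <- function(replicate, condition) {
  10 * replicate + as.integer(condition == "treated")
}

#' Simulate ground truth for a synthetic cohort
#'
#' Draws per-gene regulation classes, untreated mean ribosome loads
#' (log-uniform), baseline mRNA abundances (lognormal), signed log2 effect
#' sizes per class, per-gene gradient dispersion, oligo multiplicity and a
#' translation-apparatus flag. Treated loads are clamped to the calibrated
#' gradient range and the realized change recorded. A qRT-PCR validation
#' panel of `qpcr_genes` genes is marked, spanning the quantiles of the
#' translation change. The generator realizes the standard polysome-profiling
#' reading of gradient position: initiation-limited translation with uniform
#' elongation, so mean ribosome load is the measure of translation.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene (`sim_truth`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_genes
  classes <- sample(names(config$class_proportions), n, replace = TRUE,
                    prob = config$class_proportions)
  load_un <- exp(runif(n, log(config$load_range[1]),
                       log(config$load_range[2])))
  abundance_un <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  eff <- function(k) {
    runif(k, config$effect_range[1], config$effect_range[2])
  }
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)

  t_eff <- numeric(n)
  a_eff <- numeric(n)
  t_eff[classes == "translation_up"] <- eff(sum(classes == "translation_up"))
  t_eff[classes == "translation_down"] <-
    -eff(sum(classes == "translation_down"))
  a_eff[classes == "abundance_up"] <- eff(sum(classes == "abundance_up"))
  a_eff[classes == "abundance_down"] <- -eff(sum(classes == "abundance_down"))
  is_coupled <- classes == "coupled"
  if (any(is_coupled)) {
    s <- sgn(sum(is_coupled))
    t_eff[is_coupled] <- s * eff(sum(is_coupled))
    a_eff[is_coupled] <- s * eff(sum(is_coupled))
  }
  a_eff <- a_eff * config$abundance_effect_scale

  load_tr <- pmin(pmax(load_un * 2^t_eff, config$load_clamp[1]),
                  config$load_clamp[2])
  load_un <- pmin(pmax(load_un, config$load_clamp[1]), config$load_clamp[2])
  abundance_tr <- abundance_un * 2^a_eff

  down <- classes == "translation_down"
  apparatus <- runif(n) < ifelse(down, config$apparatus_rate_down,
                                 config$apparatus_rate_other)
  truth <- tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    class = classes,
    load_untreated = load_un,
    load_treated = load_tr,
    d_translation = log2(load_tr / load_un),
    abundance_untreated = abundance_un,
    abundance_treated = abundance_tr,
    d_abundance = a_eff,
    dispersion = runif(n, config$dispersion_range[1],
                       config$dispersion_range[2]),
    n_oligos = sample(seq_along(config$n_oligo_probs), n, replace = TRUE,
                      prob = config$n_oligo_probs),
    apparatus = apparatus,
    psilac = seq_len(n) %in% sample.int(n, min(config$psilac_genes, n))
  )
  # qPCR validation panel: picked to span the range of translation changes
  # (strongest repressed, unchanged, strongest induced), the way validation
  # genes are chosen in practice
  ord <- order(truth$d_translation)
  q <- config$qpcr_genes
  n_ext <- max(1, floor(q / 3))
  n_mid <- q - 2 * n_ext
  mid_start <- floor((n - n_mid) / 2) + 1
  idx <- ord[unique(c(seq_len(n_ext), seq(mid_start, length.out = n_mid),
                      seq(n - n_ext + 1, n)))]
  truth$qpcr_panel <- seq_len(n) %in% idx
  class(truth) <- c("sim_truth", class(truth))
  truth
}

# per-gene discretized fraction profiles (columns = genes) for one condition
fraction_profiles <- function(truth, config, condition, calib, geom) {
  load <- if (condition == "treated") truth$load_treated else
    truth$load_untreated
  abundance <- if (condition == "treated") truth$abundance_treated else
    truth$abundance_untreated
  pos <- time_to_position(ribosomes_to_time(calib, load), geom)
  f <- seq_len(config$n_fractions)
  w <- vapply(seq_len(nrow(truth)), function(g) {
    wg <- dnorm(f, mean = pos[g], sd = truth$dispersion[g])
    wg / sum(wg)
  }, numeric(config$n_fractions))
  list(weights = w, abundance = abundance, position = pos)
}

#' Simulate one gradient run
#'
#' Generates, for one (replicate, condition) gradient: jittered ribosome peak
#' times and the run's true calibration, a synthetic A260 trace (40S/60S
#' subunit bumps near the top, then `n_peaks` ribosome peaks of decaying
#' height), each transcript's discretized Gaussian fraction profile scaled by
#' its mRNA abundance with lognormal per-fraction noise, the encoded
#' two-color array feature table (pooled ratios with per-array dye
#' distortion, Gaussian log2 noise, simulated quality fields and doping
#' controls) and per-fraction qRT-PCR tables for the validation panel.
#'
#' The returned `truth_run` table holds, per gene, the noiseless encoded
#' log2 ratio and the assay-level truth it implies (fractional position,
#' elution time, encoded average ribosome number under the run's own
#' calibration) alongside the generative mean load.
#'
#' @param truth A [simulate_truth()] table.
#' @param config The matching [sim_config()].
#' @param replicate Replicate index (1-based).
#' @param condition `"untreated"` or `"treated"`.
#' @return A list with `trace`, `geometry`, `calibration`, `peak_times`,
#'   `features`, `qpcr`, and `truth_run`.
#' @export
simulate_gradient_run <- function(truth, config, replicate,
                                  condition = c("untreated", "treated")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  if (replicate < 1 || replicate > config$n_replicates) {
    abort("`replicate` out of range for this configuration")
  }
  set.seed(sub_seed(config$seed, 100 + run_stream(replicate, condition)))

  geom <- gradient_geometry(n_fractions = config$n_fractions,
                            total_time = config$total_time)
  scheme <- encoding_scheme(config$n_fractions, config$a_min, config$a_max,
                            ramp = config$ramp)

  k <- seq_len(config$n_peaks)
  peak_times <- exp((k - config$alpha) / config$beta) *
    exp(rnorm(config$n_peaks, 0, config$peak_jitter_sd))
  peak_times <- sort(peak_times)
  calib <- fit_ribosome_calibration(peak_times)

  # A260 trace: subunit bumps (outside the default search window) + ribosome
  # peaks with decaying height; monosome shift toward polysomes is implicit
  # in the transcript profiles, the trace anchors the peak calibration.
  times <- seq(0, config$total_time, by = 1.5)
  heights <- 1.0 * 0.82^(k - 1)
  absorb <- 0.05 +
    0.45 * dnorm(times, 40, 5) / dnorm(0, 0, 5) +
    0.75 * dnorm(times, 58, 5) / dnorm(0, 0, 5)
  for (i in k) {
    absorb <- absorb +
      heights[i] * dnorm(times, peak_times[i], 9) / dnorm(0, 0, 9)
  }
  trace <- a260_trace(times, absorb)

  prof <- fraction_profiles(truth, config, condition, calib, geom)
  n_genes <- nrow(truth)

  # noiseless encoded truth per gene
  a <- scheme$a
  w <- prof$weights
  y_true <- log2(colSums(w * a) / colSums(w * (1 - a)))
  pos_enc <- ratio_to_position(y_true, scheme)
  t_enc <- position_to_time(pos_enc$position, geom)
  k_enc <- time_to_ribosomes(calib, t_enc)

  # noisy measured pooled ratio per gene (fraction-level harvest noise)
  noisy <- w * matrix(prof$abundance, config$n_fractions, n_genes,
                      byrow = TRUE) *
    exp(matrix(rnorm(config$n_fractions * n_genes, 0,
                     config$fraction_noise_sdlog),
               config$n_fractions, n_genes))
  y_meas <- log2(colSums(noisy * a) / colSums(noisy * (1 - a)))

  # per-array dye distortion shared by genes and doping controls
  dye_slope <- max(0.2, 1 + rnorm(1, 0, config$dye_slope_sd))
  dye_offset <- rnorm(1, 0, config$dye_offset_sd)

  oligo_of <- rep(seq_len(n_genes), truth$n_oligos)
  oligo_idx <- unlist(lapply(truth$n_oligos, seq_len))
  n_feat <- length(oligo_of)
  feat_log2 <- dye_slope * y_meas[oligo_of] + dye_offset +
    rnorm(n_feat, 0, config$array_log2_sd)
  fails <- runif(n_feat) < config$quality_fail_rate
  pixel_r <- ifelse(fails, runif(n_feat, 0.1, 0.55), runif(n_feat, 0.8, 1.0))
  ib_hi <- ifelse(fails, runif(n_feat, 0.5, 2.4), runif(n_feat, 3, 30))
  ib_lo <- pmin(ib_hi, runif(n_feat, 0.5, 1) * ib_hi)
  cy3 <- runif(n_feat, 200, 2000)

  features <- tibble(
    feature_id = sprintf("%s_o%d", truth$gene_id[oligo_of], oligo_idx),
    gene_id = truth$gene_id[oligo_of],
    transcript_id = truth$gene_id[oligo_of],
    cy3 = cy3,
    cy5 = cy3 * 2^feat_log2,
    log2_ratio = feat_log2,
    pixel_r = pixel_r,
    ib_cy5 = ib_hi,
    ib_cy3 = ib_lo,
    is_control = FALSE,
    control_fraction = NA_integer_
  )

  dope <- assign_doping_controls(scheme, config$controls_per_fraction)
  ctl_log2 <- dye_slope * dope$expected_log2_ratio + dye_offset +
    rnorm(nrow(dope), 0, config$array_log2_sd)
  ctl_cy3 <- runif(nrow(dope), 500, 1500)
  controls <- tibble(
    feature_id = dope$control_id,
    gene_id = dope$control_id,
    transcript_id = dope$control_id,
    cy3 = ctl_cy3,
    cy5 = ctl_cy3 * 2^ctl_log2,
    log2_ratio = ctl_log2,
    pixel_r = runif(nrow(dope), 0.85, 1.0),
    ib_cy5 = runif(nrow(dope), 5, 30),
    ib_cy3 = runif(nrow(dope), 5, 30),
    is_control = TRUE,
    control_fraction = dope$fraction
  )
  features <- dplyr::bind_rows(features, controls)
  features$replicate <- replicate
  features$condition <- condition

  # qRT-PCR for the validation panel, with its own doping control
  panel <- which(truth$qpcr_panel)
  qpcr <- purrr::map_dfr(panel, function(g) {
    raw <- w[, g] * prof$abundance[g] *
      pmax(1 + rnorm(config$n_fractions, 0, config$qpcr_cv), 0.01)
    ctl <- pmax(1 + rnorm(config$n_fractions, 0, config$qpcr_cv), 0.01)
    tibble(
      gene = truth$gene_id[g],
      condition = condition,
      replicate = replicate,
      fraction = seq_len(config$n_fractions),
      mean = raw,
      se = config$qpcr_cv * raw / sqrt(3),
      control_mean = ctl,
      control_se = config$qpcr_cv * ctl / sqrt(3)
    )
  })

  load_now <- if (condition == "treated") truth$load_treated else
    truth$load_untreated
  truth_run <- tibble(
    gene_id = truth$gene_id,
    replicate = replicate,
    condition = condition,
    mean_load = load_now,
    true_log2_ratio = y_true,
    encoded_position = pos_enc$position,
    encoded_time = t_enc,
    encoded_load = k_enc
  )

  list(
    trace = trace,
    geometry = geom,
    calibration = calib,
    peak_times = peak_times,
    features = features,
    qpcr = qpcr,
    truth_run = truth_run
  )
}

#' Simulate an mRNA abundance array
#'
#' One abundance array per (replicate, condition): every gene's log2 ratio
#' against a common reference (the cohort's untreated abundance) with a
#' per-array affine dye distortion and Gaussian noise, plus spike-in controls
#' doped at known log2 ratios (-1, 0, 1) that carry the same distortion so
#' [normalize_abundance()] can undo it.
#'
#' @inheritParams simulate_gradient_run
#' @param spikes_per_level Spike-in features per known ratio level.
#' @return A list with `features` (array table) and `spike_ratios`.
#' @export
simulate_abundance_run <- function(truth, config, replicate,
                                   condition = c("untreated", "treated"),
                                   spikes_per_level = 8) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  set.seed(sub_seed(config$seed, 300 + run_stream(replicate, condition)))
  n <- nrow(truth)
  true_ratio <- if (condition == "treated") truth$d_abundance else
    rep(0, n)
  dye_slope <- max(0.2, 1 + rnorm(1, 0, config$dye_slope_sd))
  dye_offset <- rnorm(1, 0, config$dye_offset_sd)
  gene_log2 <- dye_slope * (true_ratio +
                            rnorm(n, 0, config$abundance_log2_sd)) +
    dye_offset
  cy3 <- runif(n, 200, 2000)
  genes <- tibble(
    feature_id = paste0(truth$gene_id, "_ab"),
    gene_id = truth$gene_id,
    transcript_id = truth$gene_id,
    cy3 = cy3,
    cy5 = cy3 * 2^gene_log2,
    log2_ratio = gene_log2,
    pixel_r = runif(n, 0.8, 1),
    ib_cy5 = runif(n, 3, 30),
    ib_cy3 = runif(n, 3, 30),
    is_control = FALSE,
    control_fraction = NA_integer_
  )
  levels <- c(-1, 0, 1)
  expected <- rep(levels, each = spikes_per_level)
  n_sp <- length(expected)
  sp_log2 <- dye_slope * expected + dye_offset +
    rnorm(n_sp, 0, config$abundance_log2_sd / 2)
  sp_cy3 <- runif(n_sp, 500, 1500)
  spikes <- tibble(
    feature_id = sprintf("spike_%+d_%02d", rep(levels, each = spikes_per_level),
                         rep(seq_len(spikes_per_level), times = length(levels))),
    gene_id = "spike",
    transcript_id = "spike",
    cy3 = sp_cy3,
    cy5 = sp_cy3 * 2^sp_log2,
    log2_ratio = sp_log2,
    pixel_r = runif(n_sp, 0.85, 1),
    ib_cy5 = runif(n_sp, 5, 30),
    ib_cy3 = runif(n_sp, 5, 30),
    is_control = TRUE,
    control_fraction = NA_integer_
  )
  features <- dplyr::bind_rows(genes, spikes)
  features$replicate <- replicate
  features$condition <- condition
  list(
    features = features,
    spike_ratios = tibble(feature_id = spikes$feature_id,
                          expected_log2_ratio = expected)
  )
}

#' Simulate a pulsed-SILAC peptide table
#'
#' Protein-level truth couples production change to the generative
#' translation and abundance changes:
#' log2 protein change = c_t * d_translation + c_a * d_abundance + noise.
#' Each covered protein yields 1-8 peptides per direction with per-peptide
#' quantitation noise; the reverse experiment is stored in its native flipped
#' orientation (untreated:treated). Identification probabilities and
#' curation flags are drawn so a configured fraction of peptides fails the
#' standard filters.
#'
#' @param truth A [simulate_truth()] table.
#' @param config The matching [sim_config()].
#' @return A list with `peptides` (both directions, see
#'   [read_peptide_table()] for columns) and `protein_truth` (tibble:
#'   `gene`, `protein`, `log2_protein_change`).
#' @export
simulate_psilac <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 500))
  covered <- truth[truth$psilac, , drop = FALSE]
  n <- nrow(covered)
  protein_change <- config$c_translation * covered$d_translation +
    config$c_abundance * covered$d_abundance +
    rnorm(n, 0, config$protein_log2_sd)
  protein_truth <- tibble(
    gene = covered$gene_id,
    protein = paste0("P_", covered$gene_id),
    log2_protein_change = protein_change,
    apparatus = covered$apparatus
  )
  one_direction <- function(direction) {
    n_pep <- sample(config$peptides_range[1]:config$peptides_range[2], n,
                    replace = TRUE)
    prot <- rep(seq_len(n), n_pep)
    total <- length(prot)
    sign <- if (direction == "forward") 1 else -1
    log2_pep <- sign * protein_change[prot] +
      rnorm(total, 0, config$peptide_log2_sd)
    low_prob <- runif(total) < config$prob_below_rate
    tibble(
      peptide = sprintf("%s_%s_p%02d", protein_truth$protein[prot], direction,
                        unlist(lapply(n_pep, seq_len))),
      protein = protein_truth$protein[prot],
      gene = protein_truth$gene[prot],
      unique = runif(total) < 0.95,
      prob = ifelse(low_prob, runif(total, 0.5, 0.949),
                    runif(total, 0.95, 1)),
      ratio_mh = 2^log2_pep,
      quality_ok = runif(total) >= config$peptide_quality_fail_rate,
      direction = direction
    )
  }
  peptides <- dplyr::bind_rows(one_direction("forward"),
                               one_direction("reverse"))
  list(peptides = peptides, protein_truth = protein_truth)
}

#' Simulate a complete Gradient Encoding experiment
#'
#' Runs [simulate_truth()], all gradient runs (replicates x conditions), the
#' matching abundance arrays and the pSILAC tables under a single seed.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `scheme`, `truth`, `runs` (named list of
#'   gradient runs), `abundance_runs` and `psilac`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  scheme <- encoding_scheme(config$n_fractions, config$a_min, config$a_max,
                            ramp = config$ramp)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = c("untreated", "treated"),
                      stringsAsFactors = FALSE)
  runs <- purrr::pmap(grid, function(replicate, condition) {
    simulate_gradient_run(truth, config, replicate, condition)
  })
  names(runs) <- paste0(grid$condition, "_", grid$replicate)
  abundance_runs <- purrr::pmap(grid, function(replicate, condition) {
    simulate_abundance_run(truth, config, replicate, condition)
  })
  names(abundance_runs) <- names(runs)
  list(
    config = config,
    scheme = scheme,
    truth = truth,
    runs = runs,
    abundance_runs = abundance_runs,
    psilac = simulate_psilac(truth, config)
  )
}
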