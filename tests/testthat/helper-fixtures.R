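# shared fixture builders: everything is generated in code at test time

default_scheme <- function(n = 15) encoding_scheme(n, 0.1, 0.9)

# array feature row(s) with sane quality fields
make_feature_rows <- function(feature_id, gene_id = feature_id,
                              log2_ratio = 0, pixel_r = 0.9,
                              ib_cy5 = 10, ib_cy3 = 10,
                              is_control = FALSE, control_fraction = NA_integer_) {
  cy3 <- 1000
  tibble::tibble(
    feature_id = feature_id, gene_id = gene_id, transcript_id = gene_id,
    cy5 = cy3 * 2^log2_ratio, cy3 = cy3, log2_ratio = log2_ratio,
    pixel_r = pixel_r, ib_cy5 = ib_cy5, ib_cy3 = ib_cy3,
    is_control = is_control, control_fraction = control_fraction
  )
}

# control rows covering every fraction of a scheme, measured ratios given by
# an affine transform of the expected ratios plus optional noise
make_control_rows <- function(scheme, per_fraction = 2, slope = 1,
                              intercept = 0, noise_sd = 0) {
  dope <- assign_doping_controls(scheme, per_fraction)
  measured <- slope * dope$expected_log2_ratio + intercept +
    rnorm(nrow(dope), 0, noise_sd)
  make_feature_rows(dope$control_id, dope$control_id, measured,
                    is_control = TRUE, control_fraction = dope$fraction)
}

# brute-force peak scan used as the independent oracle for find_peaks:
# every local maximum, prominence = height above the higher of the two
# deepest flanking minima before a higher point is met
brute_force_peaks <- function(times, y, min_prominence, window = range(times)) {
  thr <- min_prominence * (max(y) - min(y))
  out <- numeric(0)
  n <- length(y)
  for (i in seq(2, n - 1)) {
    if (!(y[i] > y[i - 1] && y[i] >= y[i + 1])) next
    if (times[i] < window[1] || times[i] > window[2]) next
    left <- y[seq_len(i - 1)]
    higher_left <- which(left > y[i])
    lmin <- min(left[seq(from = if (length(higher_left)) max(higher_left) + 1 else 1,
                         to = i - 1)])
    right <- y[seq(i + 1, n)]
    higher_right <- which(right > y[i])
    rmin <- min(right[seq_len(if (length(higher_right)) min(higher_right) - 1
                              else length(right))])
    if (y[i] - max(lmin, rmin) >= thr) out <- c(out, times[i])
  }
  out
}

# tiny peptide table builder
make_peptides <- function(protein, ratios, prob = 0.99, quality_ok = TRUE,
                          unique = TRUE, direction = "forward",
                          gene = protein) {
  tibble::tibble(
    peptide = paste0(protein, "_", direction, "_", seq_along(ratios)),
    protein = protein, gene = gene, unique = unique, prob = prob,
    ratio_mh = ratios, quality_ok = quality_ok, direction = direction
  )
}
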