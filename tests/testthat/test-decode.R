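test_that("quality filter applies the inclusive 0.6 / 2.5 rules", {
  rows <- dplyr::bind_rows(
    make_feature_rows("a", pixel_r = 0.55, ib_cy5 = 2.0, ib_cy3 = 2.4),
    make_feature_rows("b", pixel_r = 0.55, ib_cy5 = 2.6, ib_cy3 = 1.0),
    make_feature_rows("c", pixel_r = 0.60, ib_cy5 = 1.0, ib_cy3 = 1.0),
    make_feature_rows("d", pixel_r = 0.99, ib_cy5 = 30, ib_cy3 = 30)
  )
  res <- quality_filter(rows)
  expect_setequal(res$kept$feature_id, c("b", "c", "d"))
  expect_equal(res$rejected$feature_id, "a")
  expect_true("reason" %in% names(res$rejected))
  # exact partition
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(rows))
  expect_length(intersect(res$kept$feature_id, res$rejected$feature_id), 0)

  bad <- dplyr::select(rows, -"pixel_r")
  expect_error(quality_filter(bad), "pixel_r")
})

test_that("dye calibration recovers affine distortions of control ratios", {
  sch <- default_scheme()
  shifted <- make_control_rows(sch, 2, slope = 1, intercept = 0.3)
  fit1 <- fit_dye_calibration(shifted, sch)
  expect_equal(fit1$slope, 1, tolerance = 1e-9)
  expect_equal(fit1$intercept, 0.3, tolerance = 1e-9)

  scaled <- make_control_rows(sch, 2, slope = 1.2, intercept = -0.1)
  fit2 <- fit_dye_calibration(scaled, sch)
  expect_equal(fit2$slope, 1.2, tolerance = 1e-9)
  expect_equal(fit2$intercept, -0.1, tolerance = 1e-9)
  expect_equal(
    apply_dye_calibration(fit2, 1.2 * expected_log2_ratio(sch) - 0.1),
    expected_log2_ratio(sch), tolerance = 1e-9
  )

  one_fraction <- make_control_rows(sch, 4)
  one_fraction <- one_fraction[one_fraction$control_fraction == 5, ]
  expect_error(fit_dye_calibration(one_fraction, sch), "two distinct")
})

test_that("dye calibration slope is accurate under measurement noise", {
  sch <- default_scheme()
  set.seed(9)
  slopes <- vapply(1:100, function(i) {
    noisy <- make_control_rows(sch, 4, slope = 1.1, intercept = 0.05,
                               noise_sd = 0.05)
    fit_dye_calibration(noisy, sch)$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 1.1) < 0.05))
})

test_that("ratio_to_position inverts the expected-ratio map with clamping", {
  sch <- default_scheme()
  y <- expected_log2_ratio(sch)
  expect_equal(ratio_to_position(0, sch)$position, 8, tolerance = 1e-12)
  expect_equal(ratio_to_position(log2(0.9 / 0.1), sch)$position, 15,
               tolerance = 1e-12)
  midway <- (y[3] + y[4]) / 2
  expect_equal(ratio_to_position(midway, sch)$position, 3.5,
               tolerance = 1e-12)

  clamped <- ratio_to_position(c(y[1] - 1, y[15] + 1), sch)
  expect_equal(clamped$position, c(1, 15))
  expect_true(all(clamped$clamped))
  expect_lt(clamped$position_unclamped[1], 1)
  expect_gt(clamped$position_unclamped[2], 15)

  inside <- ratio_to_position(seq(y[1], y[15], length.out = 50), sch)
  expect_true(all(diff(inside$position) > 0))
  expect_false(any(inside$clamped))
})

test_that("regression and piecewise inversions agree on the default ramp", {
  sch <- default_scheme()
  probe <- seq(expected_log2_ratio(sch)[1], expected_log2_ratio(sch)[15],
               length.out = 101)
  pw <- ratio_to_position(probe, sch, method = "piecewise")$position
  rg <- ratio_to_position(probe, sch, method = "regression")$position
  expect_true(max(abs(pw - rg)) <= 0.05)
})

test_that("decode round-trips a transcript confined to one fraction", {
  sch <- default_scheme()
  geom <- gradient_geometry(n_fractions = 15, total_time = 450)
  calib <- fit_ribosome_calibration(exp((1:6 + 13.4) / 3.2))
  for (f in c(3, 8, 12)) {
    prof <- rep(0, 15); prof[f] <- 1
    ratio <- pool_profile(prof, sch)$true_log2_ratio
    table <- dplyr::bind_rows(
      make_feature_rows("gene1_o1", "gene1", log2_ratio = ratio),
      make_control_rows(sch, 2)
    )
    decoded <- decode_experiment(table, sch, geom, calib)
    expect_equal(decoded$position, f, tolerance = 1e-9)
    expect_equal(decoded$avg_ribosomes,
                 time_to_ribosomes(calib, fraction_midpoints(geom)[f]),
                 tolerance = 1e-9)
  }
})

test_that("doping controls decode to their assigned fractions", {
  cfg <- noiseless(sim_config(seed = 3, n_genes = 50))
  run <- simulate_gradient_run(simulate_truth(cfg), cfg, 1, "untreated")
  sch <- encoding_scheme(cfg$n_fractions, cfg$a_min, cfg$a_max)
  controls <- run$features[run$features$is_control, ]
  dye <- fit_dye_calibration(controls, sch)
  pos <- ratio_to_position(
    apply_dye_calibration(dye, controls$log2_ratio), sch
  )$position
  expect_true(all(abs(pos - controls$control_fraction) <= 0.01))
})

test_that("decode errors without controls or calibration", {
  sch <- default_scheme()
  geom <- gradient_geometry(n_fractions = 15, total_time = 450)
  calib <- fit_ribosome_calibration(exp((1:6 + 13.4) / 3.2))
  no_controls <- make_feature_rows("x_o1", "x", 0)
  expect_error(decode_experiment(no_controls, sch, geom, calib),
               "doping-control")
})

test_that("abundance normalization undoes affine spike-in distortions", {
  spikes <- make_feature_rows(sprintf("spike_%d", 1:6), "spike",
                              log2_ratio = c(-1, -1, 0, 0, 1, 1) + 0.4,
                              is_control = TRUE)
  spike_ratios <- tibble::tibble(feature_id = spikes$feature_id,
                                 expected_log2_ratio = c(-1, -1, 0, 0, 1, 1))
  genes <- make_feature_rows(sprintf("g%d_f", 1:5), sprintf("g%d", 1:5),
                             log2_ratio = c(0.4, 1.4, -0.6, 0.4, 2.4))
  res <- normalize_abundance(dplyr::bind_rows(genes, spikes), spike_ratios)
  expect_equal(res$genes$log2_abundance_ratio, c(0, 1, -1, 0, 2),
               tolerance = 1e-9)

  # slope compression is restored
  spikes2 <- spikes
  spikes2$log2_ratio <- 0.8 * spike_ratios$expected_log2_ratio
  res2 <- normalize_abundance(dplyr::bind_rows(genes, spikes2), spike_ratios)
  expect_equal(res2$calibration$slope, 0.8, tolerance = 1e-9)

  one_level <- spikes[3:4, ]
  expect_error(
    normalize_abundance(dplyr::bind_rows(genes, one_level), spike_ratios),
    "two or more"
  )
})

test_that("self-vs-self abundance arrays center near zero", {
  cfg <- sim_config(seed = 21, n_genes = 400)
  truth <- simulate_truth(cfg)
  run <- simulate_abundance_run(truth, cfg, 1, "untreated")
  res <- normalize_abundance(run$features, run$spike_ratios)
  expect_lt(abs(median(res$genes$log2_abundance_ratio)), 0.02)
})
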