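test_that("gradient geometry validates boundaries and computes midpoints", {
  geom <- gradient_geometry(c(0, 10, 20))
  expect_equal(geom$n_fractions, 2L)
  expect_equal(fraction_midpoints(geom), c(5, 15))

  eq <- gradient_geometry(n_fractions = 15, total_time = 150)
  expect_equal(fraction_midpoints(eq), seq(5, 145, by = 10))

  uneven <- gradient_geometry(c(0, 4, 20))
  expect_equal(fraction_midpoints(uneven), c(2, 12))

  expect_error(gradient_geometry(c(10, 10, 20)), "strictly increasing")
  expect_error(gradient_geometry(c(-1, 10)), "time 0")
})

test_that("a260 traces require uniform increasing times", {
  expect_s3_class(a260_trace(0:10, rep(1, 11)), "a260_trace")
  expect_error(a260_trace(c(0, 1, 1.5), c(1, 1, 1)), "uniform")
  expect_error(a260_trace(c(0, 2, 1), c(1, 1, 1)), "increasing")
  expect_error(a260_trace(0:2, c(1, -1, 1)), "nonnegative")
})

test_that("find_peaks locates gaussian peaks and ignores flat traces", {
  t <- seq(0, 300, by = 1)
  y <- dnorm(t, 100, 8) + dnorm(t, 160, 8) + dnorm(t, 205, 8)
  peaks <- find_peaks(a260_trace(t, y), min_prominence = 0.05)
  expect_length(peaks, 3)
  expect_true(all(abs(peaks - c(100, 160, 205)) <= 1))

  flat <- a260_trace(t, rep(2, length(t)))
  expect_length(find_peaks(flat, 0.05), 0)

  single <- a260_trace(t, dnorm(t, 150, 10))
  p1 <- find_peaks(single, 0.05)
  expect_length(p1, 1)
  expect_true(abs(p1 - 150) <= 1)
})

test_that("find_peaks respects the search window and prominence rule", {
  t <- seq(0, 300, by = 1)
  y <- dnorm(t, 50, 6) + 0.5 * dnorm(t, 150, 6)
  peaks <- find_peaks(a260_trace(t, y), 0.05, search_window = c(100, 300))
  expect_true(all(peaks >= 100))
  expect_length(peaks, 1)

  # shoulder peak below the prominence threshold is dropped
  y2 <- dnorm(t, 100, 10) + 0.015 * dnorm(t, 140, 4)
  big <- find_peaks(a260_trace(t, y2), min_prominence = 0.2)
  expect_length(big, 1)

  expect_error(find_peaks(a260_trace(t, y), 1.2), "min_prominence")
  expect_error(find_peaks(a260_trace(t, y), 0.05, c(-10, 500)), "within")
})

test_that("find_peaks matches an exhaustive brute-force scan", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(30:200, 1)
    t <- seq_len(n)
    y <- abs(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 2))
    y[is.na(y)] <- 0
    prom <- runif(1, 0.02, 0.3)
    expect_equal(find_peaks(a260_trace(t, y), prom),
                 sort(brute_force_peaks(t, y, prom)))
  }
})

test_that("ribosome calibration recovers generating parameters exactly", {
  alpha0 <- -10; beta0 <- 2.5
  peaks <- exp((1:6 - alpha0) / beta0)
  calib <- fit_ribosome_calibration(peaks)
  expect_equal(calib$alpha, alpha0, tolerance = 1e-9)
  expect_equal(calib$beta, beta0, tolerance = 1e-9)
  expect_equal(time_to_ribosomes(calib, peaks), 1:6, tolerance = 1e-9)

  two <- fit_ribosome_calibration(c(exp(1), exp(2)))
  expect_equal(two$alpha, 0, tolerance = 1e-12)
  expect_equal(two$beta, 1, tolerance = 1e-12)
  expect_equal(time_to_ribosomes(two, exp(3)), 3, tolerance = 1e-12)
})

test_that("calibration slope is robust to 1% time jitter", {
  beta0 <- 3.2; alpha0 <- -13.4
  truth <- exp((1:6 - alpha0) / beta0)
  set.seed(42)
  betas <- vapply(1:100, function(i) {
    jittered <- sort(truth * exp(rnorm(6, 0, 0.01)))
    fit_ribosome_calibration(jittered)$beta
  }, numeric(1))
  expect_true(all(abs(betas - beta0) / beta0 < 0.05))
})

test_that("calibration rejects degenerate inputs", {
  expect_error(fit_ribosome_calibration(100), "at least two")
  expect_error(fit_ribosome_calibration(c(-5, 100)), "positive")
  expect_error(fit_ribosome_calibration(c(200, 100)), "strictly increasing")
  calib <- fit_ribosome_calibration(c(90, 150, 260))
  expect_error(time_to_ribosomes(calib, 0), "positive")
})

test_that("time_to_ribosomes is strictly increasing and invertible", {
  calib <- fit_ribosome_calibration(exp((1:5 + 13.4) / 3.2))
  ts <- seq(40, 400, by = 7)
  ks <- time_to_ribosomes(calib, ts)
  expect_true(all(diff(ks) > 0))
  expect_equal(ribosomes_to_time(calib, ks), ts, tolerance = 1e-9)
})

test_that("position/time interpolation round-trips and extrapolates", {
  geom <- gradient_geometry(n_fractions = 15, total_time = 450)
  pos <- c(0.4, 1, 3.5, 8, 15, 15.8)
  expect_equal(time_to_position(position_to_time(pos, geom), geom), pos,
               tolerance = 1e-12)
  expect_true(all(diff(position_to_time(pos, geom)) > 0))
})

test_that("trace files round-trip through the tab-delimited format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tr <- a260_trace(seq(0, 10, 0.5), runif(21))
  write_a260_trace(tr, path)
  back <- read_a260_trace(path)
  expect_equal(back$absorbance_au, tr$absorbance_au, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(a = 1:3, b = 1:3), bad)
  expect_error(read_a260_trace(bad), "missing column")
})
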