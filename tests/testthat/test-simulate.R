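test_that("the truth draw is deterministic given the seed", {
  cfg <- sim_config(seed = 99, n_genes = 200)
  expect_identical(simulate_truth(cfg), simulate_truth(cfg))
  run_a <- simulate_gradient_run(simulate_truth(cfg), cfg, 1, "treated")
  run_b <- simulate_gradient_run(simulate_truth(cfg), cfg, 1, "treated")
  expect_identical(run_a$features, run_b$features)
  ps_a <- simulate_psilac(simulate_truth(cfg), cfg)
  ps_b <- simulate_psilac(simulate_truth(cfg), cfg)
  expect_identical(ps_a$peptides, ps_b$peptides)
  # different streams give different draws
  run_c <- simulate_gradient_run(simulate_truth(cfg), cfg, 2, "treated")
  expect_false(identical(run_a$features$log2_ratio,
                         run_c$features$log2_ratio))
})

test_that("an all-null cohort has identical loads in both conditions", {
  cfg <- sim_config(
    seed = 5, n_genes = 300,
    class_proportions = c(null = 1, translation_up = 0,
                          translation_down = 0, abundance_up = 0,
                          abundance_down = 0, coupled = 0)
  )
  truth <- simulate_truth(cfg)
  expect_equal(truth$load_treated, truth$load_untreated)
  expect_equal(truth$abundance_treated, truth$abundance_untreated)
  expect_true(all(truth$d_translation == 0))
})

test_that("class counts match configured proportions within binomial bounds", {
  props <- c(null = 0.8, translation_up = 0, translation_down = 0.2,
             abundance_up = 0, abundance_down = 0, coupled = 0)
  cfg <- sim_config(seed = 13, n_genes = 5000, class_proportions = props)
  truth <- simulate_truth(cfg)
  n_down <- sum(truth$class == "translation_down")
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.2)
  expect_gte(n_down, bounds[1])
  expect_lte(n_down, bounds[2])
  expect_error(
    sim_config(seed = 1, class_proportions = props * 0.9),
    "sum to 1"
  )
})

test_that("loads stay positive and inside the clamp range", {
  cfg <- sim_config(seed = 23, n_genes = 2000)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$load_untreated >= cfg$load_clamp[1]))
  expect_true(all(truth$load_treated <= cfg$load_clamp[2]))
  expect_true(all(truth$abundance_untreated > 0))
  expect_true(all(truth$dispersion > 0))
})

test_that("trace peaks are recoverable at the configured count", {
  cfg <- sim_config(seed = 8, n_genes = 50)
  run <- simulate_gradient_run(simulate_truth(cfg), cfg, 1, "untreated")
  peaks <- find_peaks(run$trace, 0.05, cfg$search_window)
  expect_length(peaks, cfg$n_peaks)
  # found peaks sit within one sampling step of the generating peak times
  step <- diff(run$trace$time_s)[1]
  expect_true(all(abs(peaks - run$peak_times) <= step))
})

test_that("the configured quality-failure rate is realized", {
  cfg <- sim_config(seed = 17, n_genes = 4000, quality_fail_rate = 0.05,
                    n_oligo_probs = c(0, 0, 1))  # 12000 features
  run <- simulate_gradient_run(simulate_truth(cfg), cfg, 1, "untreated")
  genes_only <- run$features[!run$features$is_control, ]
  res <- quality_filter(genes_only)
  frac <- nrow(res$rejected) / nrow(genes_only)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("the configured low-probability peptide rate is realized", {
  cfg <- sim_config(seed = 19, n_genes = 2000, psilac_genes = 1500,
                    prob_below_rate = 0.10, peptide_quality_fail_rate = 0)
  sim <- simulate_psilac(simulate_truth(cfg), cfg)
  frac <- mean(sim$peptides$prob < 0.95)
  n <- nrow(sim$peptides)
  bounds <- qbinom(c(0.005, 0.995), n, 0.10) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  res <- filter_peptide_table(sim$peptides)
  expect_equal(nrow(res$rejected) / n, frac, tolerance = 1e-12)
})

test_that("noiseless pSILAC with unit couplings reproduces truth exactly", {
  cfg <- noiseless(sim_config(seed = 25, n_genes = 300, psilac_genes = 200))
  truth <- simulate_truth(cfg)
  sim <- simulate_psilac(truth, cfg)
  comb <- combine_forward_reverse(
    protein_log_ratios(sim$peptides, "forward"),
    protein_log_ratios(sim$peptides, "reverse")
  )
  merged <- dplyr::inner_join(comb, sim$protein_truth,
                              by = c("protein", "gene"))
  expect_equal(merged$log2_ratio, merged$log2_protein_change,
               tolerance = 1e-9)
  tmerged <- dplyr::inner_join(
    merged, truth, by = c(gene = "gene_id")
  )
  expect_equal(tmerged$log2_protein_change,
               tmerged$d_translation + tmerged$d_abundance,
               tolerance = 1e-9)
})

test_that("the qPCR panel spans the range of translation changes", {
  cfg <- sim_config(seed = 29)
  truth <- simulate_truth(cfg)
  panel <- truth[truth$qpcr_panel, ]
  expect_equal(nrow(panel), cfg$qpcr_genes)
  expect_lt(min(panel$d_translation), -0.5)
  expect_gt(max(panel$d_translation), 0.5)
})

test_that("sub-seeds stay within integer range for large master seeds", {
  s <- sub_seed(2^30, 531)
  expect_true(is.integer(s))
  expect_lt(s, 2^31)
  expect_gte(s, 0)
})
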