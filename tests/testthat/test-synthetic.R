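# Synthetic generator: contracts, closed-form oracles, determinism.

test_that("stress items have the contracted shape, range and latent trait", {
  st <- generate_stress_items(72, 6, 0.4, seed = 42)
  expect_identical(dim(st$items), c(72L, 6L))
  expect_true(all(st$items %in% 1:5))
  expect_true(is.integer(st$items))
  expect_length(st$latent_stress, 72)
  expect_error(generate_stress_items(10, 6, 1.2, seed = 1), "interitem_corr")
  expect_error(generate_stress_items(10, 1, 0.3, seed = 1), "n_items")
})

test_that("simulated Cronbach alpha matches the Spearman-Brown closed form", {
  # k = 6 items at observed inter-item r = 0.4: alpha = 6*0.4/(1 + 5*0.4) = 0.80
  st <- generate_stress_items(2000, 6, 0.4, seed = 7)
  expect_equal(cronbach_alpha(st$items), 0.80, tolerance = 0.05 / 0.80)
  # observed inter-item correlation itself is calibrated to the request
  r_bar <- mean(cor(st$items)[upper.tri(diag(6))])
  expect_equal(r_bar, 0.4, tolerance = 0.1)
})

test_that("expected pairwise correlation follows sqrt(w_i w_j)", {
  expect_identical(expected_pairwise_correlation(0.25, 0.25), 0.25)
  expect_identical(expected_pairwise_correlation(0, 0.7), 0)
  expect_identical(expected_pairwise_correlation(0.16, 0.36), 0.24)
  expect_error(expected_pairwise_correlation(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(expected_pairwise_correlation(0.5, 1.2), "\\[0, 1\\]")
})

test_that("long-series pairwise correlation converges to the closed form", {
  # two subjects with w = 0.16 and 0.36: expected r = 0.24
  cfg <- synthetic_config(n_subjects = 3, run_lengths = 5000, n_rois = 1,
                          base_shared_fraction = 0.16, annak_coupling = 0.20,
                          seed = 5)
  stress <- c(0, 0.5, 1)  # normalized as-is by min-max
  g <- generate_timeseries(cfg, latent_stress = stress)
  expect_equal(g$truth$effective_weight[1, 1, 1], 0.16)
  expect_equal(g$truth$effective_weight[3, 1, 1], 0.36)
  ts <- roi_matrix(g$data, "roi1")
  expect_equal(cor(ts[1, ], ts[3, ]), 0.24, tolerance = 0.03 / 0.24)
})

test_that("no shared signal gives near-zero mean ISC; w0 = 1 clips to 0.95", {
  g0 <- one_roi_dataset(20, 400, 0, seed = 11)
  m <- pairwise_isc(roi_matrix(g0$data, "roi1"))
  z <- m[upper.tri(m)]
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z)), 3 * se + 1 / sqrt(397))
  g1 <- one_roi_dataset(6, 400, 1, seed = 12)
  expect_true(all(g1$truth$effective_weight == 0.95))
  r <- tanh(pairwise_isc(roi_matrix(g1$data, "roi1")))
  expect_equal(mean(r[upper.tri(r)]), 0.95, tolerance = 0.02)
})

test_that("generated runs are near zero-mean unit-variance and reproducible", {
  cfg <- synthetic_config(n_subjects = 5, run_lengths = c(2000, 2000),
                          n_rois = 2, base_shared_fraction = 0.3, seed = 3)
  g <- generate_timeseries(cfg)
  x <- roi_matrix(g$data, "roi1", "video1")
  expect_equal(mean(x[1, ]), 0, tolerance = 0.12)
  expect_equal(sd(x[1, ]), 1, tolerance = 0.08)
  g2 <- generate_timeseries(cfg)
  expect_identical(g$data$series, g2$data$series)
  cfg_b <- cfg; cfg_b$seed <- 4L
  g3 <- generate_timeseries(cfg_b)
  expect_false(identical(g$data$series[[1]], g3$data$series[[1]]))
})

test_that("positive coupling makes pair correlation increase with min stress", {
  g <- one_roi_dataset(30, 500, 0.05, beta = 0.6, seed = 21)
  m <- tanh(pairwise_isc(roi_matrix(g$data, "roi1")))
  s <- g$truth$normalized_stress
  pair_min <- outer(s, s, pmin)[upper.tri(m)]
  r <- m[upper.tri(m)]
  hi <- r[pair_min > quantile(pair_min, 0.75)]
  lo <- r[pair_min < quantile(pair_min, 0.25)]
  expect_gt(mean(hi), mean(lo))
  # and rank correlation with the closed-form expectation is strongly positive
  w <- g$truth$effective_weight[, 1, 1]
  expected_r <- outer(w, w, expected_pairwise_correlation)[upper.tri(m)]
  expect_gt(cor(r, expected_r, method = "spearman"), 0.5)
})

test_that("fixture write/read round-trips and is atomic", {
  cfg <- synthetic_config(n_subjects = 4, run_lengths = c(20, 20), n_rois = 2,
                          base_shared_fraction = 0.2, seed = 8)
  ds <- generate_dataset(cfg)
  d <- withr::local_tempdir()
  mf <- write_fixture(ds$data, ds$behavioral, ds$truth, d)
  expect_identical(mf$seed, 8L)
  fx <- read_fixture(d)
  expect_equal(fx$data$series, lapply(ds$data$series, signif, 6),
               tolerance = 1e-12, ignore_attr = FALSE)
  expect_identical(fx$behavioral$subject_id, ds$behavioral$subject_id)
  expect_equal(fx$data$runs, ds$data$runs)
  expect_equal(unlist(fx$truth$latent_stress), ds$truth$latent_stress,
               tolerance = 1e-12)
  # regeneration with the same seed gives byte-identical numeric content
  d2 <- withr::local_tempdir()
  ds2 <- generate_dataset(cfg)
  write_fixture(ds2$data, ds2$behavioral, ds2$truth, d2)
  f <- "sub-001_timeseries.tsv"
  expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
  # missing directory: error, and nothing is created
  miss <- file.path(d, "does", "not", "exist")
  expect_error(write_fixture(ds$data, ds$behavioral, ds$truth, miss),
               "does not exist")
  expect_false(dir.exists(miss))
})
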