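# Pairwise ISC, summaries, bootstrap, condition and group comparisons.

test_that("pairwise ISC clips duplicates, sees orthogonality, counts pairs", {
  t_axis <- seq(0, 4 * pi, length.out = 200)
  ts <- rbind(a = sin(t_axis), b = sin(t_axis), c = cos(t_axis))
  m <- pairwise_isc(ts)
  expect_equal(m["a", "b"], atanh(1 - 1e-7))   # r = 1, clipped but finite
  expect_lt(abs(m["a", "c"]), 0.05)            # whole periods: r ~ 0
  expect_identical(sum(upper.tri(m)), 3L)      # n(n-1)/2 = 3 unique pairs
  expect_true(all(is.na(diag(m))))
  expect_error(pairwise_isc(rbind(a = rep(1, 10), b = rnorm(10), c = rnorm(10))),
               "constant.*a")
  expect_error(pairwise_isc(ts[, 1:2]), "time points")
})

test_that("ISC is invariant to per-subject positive affine transforms", {
  set.seed(9)
  ts <- matrix(rnorm(5 * 80), 5, 80)
  m0 <- pairwise_isc(ts)
  ts2 <- ts * c(2, 0.5, 10, 1, 3) + c(-1, 4, 0, 100, 2)
  expect_equal(unclass(pairwise_isc(ts2)), unclass(m0), tolerance = 1e-12)
  # reordering subjects permutes the matrix consistently
  pm <- c(3, 1, 5, 2, 4)
  m_p <- pairwise_isc(ts[pm, ])
  expect_equal(unclass(m_p), unclass(m0)[pm, pm], tolerance = 1e-12)
  expect_equal(summarize_isc(m_p), summarize_isc(m0))
})

test_that("run concatenation z-scores segments and is duplication-invariant", {
  cfg <- synthetic_config(n_subjects = 5, run_lengths = c(60, 60), n_rois = 2,
                          base_shared_fraction = 0.4, seed = 13)
  g <- generate_timeseries(cfg)
  cc <- concatenate_runs(g$data, c("video1", "video2"))
  expect_identical(sum(cc$runs$length), 120L)
  seg <- roi_matrix(cc, "roi1", "video1")
  expect_equal(unname(rowMeans(seg)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(seg, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # concatenating two copies of one run doubles length, leaves ISC unchanged
  dup <- concatenate_runs(g$data, c("video1", "video1"))
  expect_identical(sum(dup$runs$length), 120L)
  m_dup <- pairwise_isc(roi_matrix(dup, "roi1"))
  m_one <- pairwise_isc(roi_matrix(concatenate_runs(g$data, "video1"), "roi1"))
  expect_equal(unclass(m_dup), unclass(m_one), tolerance = 1e-10)
  expect_error(concatenate_runs(g$data, "nope"), "unknown run")
})

test_that("summaries back-transform mean z and respect constant matrices", {
  z <- matrix(0.1, 4, 4)
  m <- iscrsa:::as_isc_matrix(z)
  expect_equal(summarize_isc(m), tanh(0.1))
  r_const <- 0.3
  m2 <- iscrsa:::as_isc_matrix(matrix(atanh(r_const), 5, 5))
  expect_equal(summarize_isc(m2), r_const)
  zs <- matrix(0, 4, 4); zs[1, 2] <- 0.5; zs[3, 4] <- -0.5
  zs <- zs + t(zs)
  expect_equal(summarize_isc(iscrsa:::as_isc_matrix(zs)), 0)
})

test_that("bootstrap is deterministic, attains the minimum p under strong
           synchrony, and keeps the Fisher-z summary", {
  g <- one_roi_dataset(12, 150, 0.95, seed = 17)
  m <- pairwise_isc(roi_matrix(g$data, "roi1"))
  b1 <- bootstrap_isc_test(m, 200, seed = 5)
  b2 <- bootstrap_isc_test(m, 200, seed = 5)
  expect_identical(b1$p, b2$p)
  expect_equal(b1$p, 1 / 201)          # observed exceeds every centered draw
  expect_equal(b1$observed, summarize_isc(m))
  b3 <- bootstrap_isc_test(m, 200, seed = 6)
  expect_lt(abs(b3$p - b1$p), 0.05)    # only Monte-Carlo noise
  expect_error(bootstrap_isc_test(m, 50, seed = 1), "100")
})

test_that("bootstrap under the null never exceeds the nominal level", {
  # the subject-wise scheme is conservative: rejection rate stays below alpha
  p <- vapply(1:40, function(s) {
    g <- one_roi_dataset(15, 120, 0, seed = 900 + s)
    m <- pairwise_isc(roi_matrix(g$data, "roi1"))
    bootstrap_isc_test(m, 300, seed = s)$p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.09)
})

test_that("Friedman on subject pairs matches hand-computed examples", {
  # identical matrices: all ranks tied, chi-square 0
  z <- matrix(rnorm(16), 4, 4); z <- z + t(z)
  m <- iscrsa:::as_isc_matrix(z)
  ft0 <- friedman_across_conditions(list(m, m, m))
  expect_equal(ft0$chi2, 0)
  expect_identical(ft0$n_pairs, 6L)
  # 3 pairs x 3 conditions with consistent ordering: rank sums (3, 6, 9),
  # chi2 = 12/(N k (k+1)) * sum (R_c - N(k+1)/2)^2 = 6
  mk <- function(v) {
    zz <- matrix(0, 3, 3)
    zz[upper.tri(zz)] <- v
    iscrsa:::as_isc_matrix(zz + t(zz))
  }
  ft <- friedman_across_conditions(list(mk(c(1, 1, 1)), mk(c(2, 2, 2)),
                                        mk(c(3, 3, 3))))
  expect_equal(ft$chi2, 6)
  expect_identical(ft$df, 2L)
  # 72 subjects would contribute 72*71/2 = 2556 pair observations
  expect_identical(choose(72, 2), 2556)
  expect_error(friedman_across_conditions(list(m, m)), "k >= 3")
})

test_that("Wilcoxon signed-rank matches the hand-ranked example and wilcox.test", {
  # d = (+1, -2, +3, -4, +5): ranks 1..5, W+ = 9, W- = 6, W = 6
  x <- c(1, 0, 3, 0, 5); y <- c(0, 2, 0, 4, 0)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$W_plus, 9)
  expect_equal(w$W_minus, 6)
  expect_equal(w$W, 6)
  expect_equal(w$z, (9 - 5 * 6 / 4) / sqrt(5 * 6 * 11 / 24))
  # d all positive: W- = 0, W = 0
  w2 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(w2$W, 0)
  # identical vectors: p = 1 with a warning
  expect_warning(w3 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(w3$p, 1)
  # agrees with the normal-approximation reference implementation
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(30); b <- rnorm(30, 0.3)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$W_plus, unname(ref$statistic))
  }
})

test_that("BH-FDR matches the hand example and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # q monotone in sorted p
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("group ISC difference finds a real group effect and validates sizes", {
  w0 <- c(rep(0.4, 10), rep(0, 10))
  cfg <- synthetic_config(n_subjects = 20, run_lengths = 200, n_rois = 1,
                          base_shared_fraction = 0, annak_coupling = 0.4,
                          seed = 19)
  # use coupling on a two-level stress vector to give group A weight 0.4
  g <- generate_timeseries(cfg, latent_stress = c(rep(1, 10), rep(0, 10)))
  expect_equal(unname(g$truth$effective_weight[1, 1, 1]), 0.4)
  res <- group_isc_difference(g$data, labels = c(rep(1, 10), rep(0, 10)),
                              n_permutations = 300, seed = 3)
  expect_gt(res$observed_diff[1], 0)
  expect_lt(res$p[1], 0.05)
  res2 <- group_isc_difference(g$data, labels = c(rep(1, 10), rep(0, 10)),
                               n_permutations = 300, seed = 3)
  expect_identical(res$p, res2$p)
  expect_error(group_isc_difference(g$data, c(rep(1, 2), rep(0, 18)),
                                    n_permutations = 300, seed = 1),
               "at least 3")
})
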