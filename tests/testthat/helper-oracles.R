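# Independent brute-force oracles used to cross-check the implementation.

# BH step-up by direct definition: for each hypothesis, the smallest alpha
# (searched over all candidate rejection thresholds) at which the plain
# step-up rule rejects it.
bh_reject_at <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= seq_len(m) * alpha / m)
  if (length(k) == 0L) return(rep(FALSE, m))
  p <= s[max(k)]
}

bh_oracle <- function(p) {
  m <- length(p)
  cand <- sort(unique(c(as.vector(outer(p, seq_len(m), function(pp, j) m * pp / j)), 1)))
  cand <- cand[cand <= 1]
  vapply(seq_len(m), function(i) {
    ok <- vapply(cand, function(a) bh_reject_at(p, a)[i], logical(1L))
    min(cand[ok])
  }, numeric(1L))
}

# Sphere mask by exhaustive scan of the whole lattice.
sphere_oracle_count <- function(center_mm, radius_mm, dims, voxel, origin) {
  cnt <- 0L
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1)) for (k in 0:(dims[3] - 1)) {
    mm <- origin + voxel * c(i, j, k)
    if (sum((mm - center_mm)^2) <= radius_mm^2 + 1e-9) cnt <- cnt + 1L
  }
  cnt
}

# Two standardized columns with exact sample correlation r (n-1 variances
# equal), built from an orthonormal pair.
two_items_with_corr <- function(r, n = 10L) {
  x <- seq_len(n)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  a <- as.numeric(scale(x))
  b <- as.numeric(scale(e))
  cbind(a, r * a + sqrt(1 - r^2) * b)
}

# Small single-ROI synthetic ensemble via the package generator.
one_roi_dataset <- function(n, t_len, w0, beta = 0, seed = 1L, n_runs = 1L) {
  cfg <- synthetic_config(n_subjects = n, run_lengths = rep(t_len, n_runs),
                          n_rois = 1L, base_shared_fraction = w0,
                          annak_coupling = beta, seed = seed)
  generate_timeseries(cfg)
}
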