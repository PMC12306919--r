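# Pairwise intersubject correlation (ISC): subject x subject Fisher-z
# matrices per ROI and condition, summaries, subject-wise bootstrap
# inference, and comparisons across conditions and groups.

#' Pairwise ISC matrix for one ROI and condition
#'
#' Computes the Pearson correlation between every pair of subjects' time
#' series and stores Fisher z = atanh(r) values; r is clipped to
#' +/- (1 - 1e-7) first so duplicated or near-duplicate series stay finite.
#' The diagonal is left undefined (NA).
#'
#' @param ts subjects x time numeric matrix (rownames = subject ids).
#' @param roi,condition optional labels carried in attributes.
#' @return an `isc_matrix`: symmetric n x n matrix of Fisher-z values with
#'   NA diagonal and attributes `roi`, `condition`.
#' @export
pairwise_isc <- function(ts, roi = NULL, condition = NULL) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  if (n < 3) stop_param("need at least 3 subjects, got %d", n)
  if (ncol(ts) < 3) stop_param("need at least 3 time points, got %d", ncol(ts))
  sdv <- apply(ts, 1L, stats::sd)
  if (any(sdv == 0)) {
    bad <- rownames(ts)[which(sdv == 0)[1L]] %||% as.character(which(sdv == 0)[1L])
    stop_param("constant time series for subject %s", bad)
  }
  z <- fisher_z(stats::cor(t(ts)))
  diag(z) <- NA_real_
  structure(z, class = c("isc_matrix", "matrix"),
            roi = roi, condition = condition)
}

as_isc_matrix <- function(z, roi = NULL, condition = NULL) {
  diag(z) <- NA_real_
  structure(z, class = c("isc_matrix", "matrix"), roi = roi,
            condition = condition)
}

#' Per-ROI pairwise ISC matrices for a time-series set
#'
#' @param set a [subject_ts_set()].
#' @param segments run names to analyze (`NULL` = full series); passed to
#'   [roi_matrix()].
#' @param condition condition label stored on each matrix.
#' @return named list of [pairwise_isc()] matrices, one per ROI.
#' @export
isc_by_roi <- function(set, segments = NULL, condition = NULL) {
  stopifnot(inherits(set, "subject_ts_set"))
  out <- lapply(set$roi_labels, function(roi)
    pairwise_isc(roi_matrix(set, roi, segments), roi = roi,
                 condition = condition))
  names(out) <- set$roi_labels
  out
}

#' Summarize a pairwise ISC matrix to a single score on the r scale
#'
#' Mean (or median) of the off-diagonal upper-triangle Fisher-z values,
#' back-transformed with tanh.
#'
#' @param m an `isc_matrix`.
#' @param method `"mean_z"` (default) or `"median_z"`.
#' @return the ISC score (an r value).
#' @export
summarize_isc <- function(m, method = c("mean_z", "median_z")) {
  method <- match.arg(method)
  if (nrow(m) < 3) stop_param("need at least 3 subjects")
  z <- upper_tri_values(m)
  inv_fisher_z(if (method == "mean_z") mean(z) else stats::median(z))
}

# Summary of a subject-resampled matrix: re-index rows/columns by `idx`,
# drop off-diagonal cells that refer to the same original subject.
resampled_summary <- function(z, idx, median_z = FALSE) {
  zi <- z[idx, idx]
  keep <- outer(idx, idx, "!=")[upper.tri(zi)]
  v <- zi[upper.tri(zi)][keep]
  if (length(v) == 0L) return(NA_real_)
  if (median_z) stats::median(v) else mean(v)
}

#' Subject-wise bootstrap test of an ISC summary
#'
#' Each iteration resamples subject indices with replacement and re-indexes
#' the stored Fisher-z matrix; off-diagonal entries that refer to the same
#' original subject (self-pairs created by the resampling) are excluded,
#' since their r = 1 would mechanically inflate synchrony. The null
#' distribution is the bootstrap summaries re-centered to zero by
#' subtracting their mean, and the two-sided p-value is
#' (1 + #\{|null| >= |observed|\}) / (n_iterations + 1). Degenerate
#' resamples (all entries excluded) are redrawn and counted.
#'
#' @param m an `isc_matrix` from [pairwise_isc()].
#' @param n_iterations bootstrap iterations (>= 100; 5000 is typical).
#' @param seed integer seed.
#' @param summary `"mean_z"` or `"median_z"`.
#' @return list of class `isc_bootstrap`: `roi`, `observed` (ISC score on the
#'   r scale), `observed_z`, `p`, `n_iterations`, `n_redrawn`, `seed`.
#' @export
bootstrap_isc_test <- function(m, n_iterations = 5000L, seed = 1L,
                               summary = c("mean_z", "median_z")) {
  summary <- match.arg(summary)
  n <- nrow(m)
  if (n < 3) stop_param("need at least 3 subjects")
  if (n_iterations < 100) stop_param("n_iterations must be >= 100")
  med <- summary == "median_z"
  obs_z <- if (med) stats::median(upper_tri_values(m)) else mean(upper_tri_values(m))
  z <- unclass(m)
  boot <- numeric(n_iterations)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_iterations)) {
      repeat {
        s <- resampled_summary(z, sample.int(n, n, replace = TRUE), med)
        if (!is.na(s)) break
        n_redrawn <- n_redrawn + 1L
      }
      boot[b] <- s
    }
  })
  null <- boot - mean(boot)
  p <- (1 + sum(abs(null) >= abs(obs_z))) / (n_iterations + 1)
  structure(list(roi = attr(m, "roi"), condition = attr(m, "condition"),
                 observed = inv_fisher_z(obs_z), observed_z = obs_z,
                 p = p, n_iterations = as.integer(n_iterations),
                 n_redrawn = n_redrawn, seed = as.integer(seed)),
            class = "isc_bootstrap")
}

#' Friedman omnibus test of ISC across conditions
#'
#' The observation unit is the unordered subject pair: each pair contributes
#' one Fisher-z value per condition, ranked within pair (average ranks for
#' ties), and the tie-corrected Friedman chi-square with k - 1 degrees of
#' freedom is computed. Pairs sharing a subject are not independent; the
#' statistic is reported as is and that dependence should be kept in mind
#' when interpreting p-values.
#'
#' @param matrices list of `isc_matrix` objects, one per condition (k >= 3),
#'   all over the same subjects in the same order.
#' @return list: `chi2`, `df`, `p`, `n_pairs`, `k`.
#' @export
friedman_across_conditions <- function(matrices) {
  k <- length(matrices)
  if (k < 3)
    stop_param("need k >= 3 conditions (use wilcoxon_signed_rank for k = 2)")
  n <- nrow(matrices[[1L]])
  for (m in matrices)
    if (!identical(dim(m), dim(matrices[[1L]])))
      stop_param("all condition matrices must cover the same subject pairs")
  pair_vals <- vapply(matrices, upper_tri_values, numeric(n * (n - 1) / 2))
  ft <- stats::friedman.test(as.matrix(pair_vals))
  chi2 <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(chi2)) {  # every pair fully tied across conditions: no differences
    chi2 <- 0
    p <- 1
  }
  list(chi2 = chi2, df = as.integer(unname(ft$parameter)),
       p = p, n_pairs = nrow(pair_vals), k = k)
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Zero differences are dropped; |d| is ranked with average ranks for ties;
#' W = min(W+, W-) is reported with the z statistic
#' (W+ - n(n+1)/4) / sqrt(V), where V = n(n+1)(2n+1)/24 - sum(t^3 - t)/48
#' over tie groups, and a two-sided normal p-value.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list: `W`, `W_plus`, `W_minus`, `z`, `p`, `n_used` (non-zero
#'   differences).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, W_plus = 0, W_minus = 0, z = 0, p = 1, n_used = 0L))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - n * (n + 1) / 4) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  list(W = min(w_plus, w_minus), W_plus = w_plus, W_minus = w_minus,
       z = z, p = min(p, 1), n_used = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: q_(i) = min_(j >= i) m p_(j) / j, mapped back to input
#' order, so q >= p elementwise.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop_param("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop_param("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Permutation test of an ISC difference between two subject groups
#'
#' The observed statistic per ROI is mean within-group-A Fisher z minus mean
#' within-group-B Fisher z (between-group pairs are unused). The null is
#' formed by randomly relabeling subjects with group sizes fixed; two-sided
#' p with +1 smoothing.
#'
#' @param set a [subject_ts_set()].
#' @param labels binary vector (0/1 or logical), one per subject; group A is
#'   `labels == 1`.
#' @param segments run names to analyze (`NULL` = full series).
#' @param n_permutations count (>= 100 recommended).
#' @param seed integer seed.
#' @return data.frame with one row per ROI: `roi`, `observed_diff` (z scale),
#'   `p`, plus attributes `n_A`, `n_B`, `seed`.
#' @export
group_isc_difference <- function(set, labels, segments = NULL,
                                 n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(set, "subject_ts_set"))
  labels <- as.integer(as.logical(labels))
  n <- length(set$series)
  if (length(labels) != n) stop_param("labels must have one entry per subject")
  if (sum(labels == 1L) < 3 || sum(labels == 0L) < 3)
    stop_param("each group needs at least 3 subjects for a within-group ISC")
  mats <- isc_by_roi(set, segments)
  ut <- upper.tri(matrix(0, n, n))
  stat <- function(z, lab) {
    a <- outer(lab == 1L, lab == 1L, "&")[ut]
    b <- outer(lab == 0L, lab == 0L, "&")[ut]
    v <- z[ut]
    mean(v[a]) - mean(v[b])
  }
  obs <- vapply(mats, function(m) stat(unclass(m), labels), numeric(1L))
  perms <- with_seed(seed, {
    replicate(n_permutations, sample(labels))
  })
  p <- vapply(seq_along(mats), function(j) {
    z <- unclass(mats[[j]])
    null <- vapply(seq_len(n_permutations),
                   function(b) stat(z, perms[, b]), numeric(1L))
    (1 + sum(abs(null) >= abs(obs[j]))) / (n_permutations + 1)
  }, numeric(1L))
  out <- data.frame(roi = set$roi_labels, observed_diff = unname(obs),
                    p = p, stringsAsFactors = FALSE)
  attr(out, "n_A") <- sum(labels == 1L)
  attr(out, "n_B") <- sum(labels == 0L)
  attr(out, "seed") <- as.integer(seed)
  out
}
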