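# Intersubject representational similarity analysis: Spearman correlation
# between the vectorized upper triangles of a neural ISC matrix and a
# behavioral similarity matrix, with subject-level (Mantel-style)
# permutation inference.

check_matrix_pair <- function(neural, behav) {
  if (!identical(dim(neural), dim(behav)))
    stop_param("neural and behavioral matrices must have identical dimensions")
  n <- nrow(neural)
  if (n < 4) stop_param("need at least 4 subjects, got %d", n)
  nb <- rownames(neural); bb <- rownames(behav)
  if (!is.null(nb) && !is.null(bb) && !identical(nb, bb))
    stop_param("subject orderings of the two matrices differ")
  n
}

#' IS-RSA score: Spearman correlation of two similarity matrices
#'
#' Spearman rank correlation (average ranks for ties) between the strict
#' upper triangles of the neural Fisher-z ISC matrix and the behavioral
#' similarity matrix. Because Spearman operates on ranks, it is invariant to
#' any strictly monotone transform of either matrix's entries — the z vs r
#' scale of the neural matrix does not matter.
#'
#' @param neural `isc_matrix` (subject x subject Fisher-z values).
#' @param behav `similarity_matrix` over the same subjects in the same order.
#' @return Spearman rho.
#' @export
isrsa_score <- function(neural, behav) {
  check_matrix_pair(neural, behav)
  x <- upper_tri_values(unclass(neural))
  y <- upper_tri_values(unclass(behav))
  if (min(y) == max(y))
    stop_param("behavioral similarity triangle is constant; rho is undefined")
  if (min(x) == max(x))
    stop_param("neural similarity triangle is constant; rho is undefined")
  stats::cor(rank(x), rank(y))
}

#' Mantel-style subject permutation test for IS-RSA
#'
#' Permutes subject labels of the behavioral matrix — rows and columns
#' jointly, preserving the dependence between entries that share a subject —
#' and recomputes the Spearman IS-RSA score each time. Two-sided p with +1
#' smoothing: (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_permutations + 1).
#'
#' @inheritParams isrsa_score
#' @param n_permutations count >= 100 (default 5000).
#' @param seed integer seed.
#' @return list of class `isrsa_test`: `rho`, `p`, `n_permutations`, `seed`,
#'   `roi`, `condition` (labels inherited from the neural matrix).
#' @export
mantel_permutation_test <- function(neural, behav, n_permutations = 5000L,
                                    seed = 1L) {
  n <- check_matrix_pair(neural, behav)
  if (n_permutations < 100) stop_param("n_permutations must be >= 100")
  rho_obs <- isrsa_score(neural, behav)
  ut <- upper.tri(matrix(0, n, n))
  x_rank <- rank(unclass(neural)[ut])
  b <- unclass(behav)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      pm <- sample.int(n)
      stats::cor(x_rank, rank(b[pm, pm][ut]))
    }, numeric(1L))
  })
  p <- (1 + sum(abs(null) >= abs(rho_obs))) / (n_permutations + 1)
  structure(list(rho = rho_obs, p = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 roi = attr(neural, "roi"), condition = attr(neural, "condition")),
            class = "isrsa_test")
}

#' Paired t contrast of two IS-RSA profiles across ROIs
#'
#' Classic paired-samples t test on ROI-wise differences of IS-RSA scores
#' (df = number of ROIs - 1), used to ask whether one condition shows
#' systematically stronger trait-synchrony coupling than another across the
#' ROI set.
#'
#' @param scores_a,scores_b per-ROI IS-RSA scores, equal length >= 2.
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_profile <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop_param("need two equal-length score vectors (length >= 2)")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) stop_param("zero variance of differences")
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' IS-RSA battery across ROIs and conditions
#'
#' Runs [mantel_permutation_test()] for every ROI of every condition and
#' applies Benjamini-Hochberg FDR across the ROI family within each
#' condition.
#'
#' @param neural_matrices list of conditions, each a named list of
#'   `isc_matrix` objects per ROI (as from [isc_by_roi()]).
#' @param behav a `similarity_matrix`.
#' @param n_permutations,seed passed to [mantel_permutation_test()]; the seed
#'   is varied deterministically per ROI/condition.
#' @return data.frame: `condition`, `roi`, `rho`, `p`, `q`,
#'   `n_permutations`, `seed`.
#' @export
isrsa_battery <- function(neural_matrices, behav, n_permutations = 5000L,
                          seed = 1L) {
  if (is.null(names(neural_matrices)))
    stop_param("neural_matrices must be a named list of conditions")
  out <- list()
  for (ci in seq_along(neural_matrices)) {
    cond <- names(neural_matrices)[ci]
    mats <- neural_matrices[[ci]]
    rows <- lapply(seq_along(mats), function(ri) {
      sd_i <- derive_seed(seed, ci * 24L + (ri - 1L) %% 24L)
      tst <- mantel_permutation_test(mats[[ri]], behav,
                                     n_permutations = n_permutations,
                                     seed = sd_i)
      data.frame(condition = cond,
                 roi = names(mats)[ri] %||% as.character(ri),
                 rho = tst$rho, p = tst$p,
                 n_permutations = tst$n_permutations, seed = sd_i,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$q <- bh_fdr(df$p)
    out[[cond]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("condition", "roi", "rho", "p", "q", "n_permutations", "seed")]
}
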