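# Behavioral scoring: perceived-stress composite, reliability, descriptives,
# and subject x subject similarity matrices under the Anna Karenina model.

validate_items <- function(items, levels = 5L) {
  items <- as.matrix(items)
  if (anyNA(items))
    stop_param("missing item responses; exclude incomplete subjects explicitly")
  if (any(items < 1 | items > levels) || any(items != round(items)))
    stop_param("item responses must be integers in 1..%d", levels)
  items
}

#' Score the perceived-stress composite
#'
#' Reverse-keyed items are mapped x -> 6 - x first, then the composite is the
#' plain mean of the (possibly re-keyed) items, so it lies in \[1, 5\] with
#' higher scores indicating higher stress. No reverse keys are applied by
#' default.
#'
#' @param items subjects x k matrix of integer responses in 1..5.
#' @param reverse_keys integer indices of reverse-keyed item columns.
#' @return numeric vector of per-subject composite scores.
#' @export
score_stress <- function(items, reverse_keys = integer(0)) {
  items <- validate_items(items)
  if (length(reverse_keys)) {
    if (any(reverse_keys < 1 | reverse_keys > ncol(items)))
      stop_param("reverse_keys out of range")
    items[, reverse_keys] <- 6L - items[, reverse_keys]
  }
  rowMeans(items)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of item sums),
#' with n-1 sample variances.
#'
#' @param items subjects x k numeric matrix, k >= 2, n >= 3.
#' @return alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop_param("need at least 2 items")
  if (nrow(items) < 3) stop_param("need at least 3 subjects")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0)
    stop_param("zero variance of item sums; alpha is undefined")
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / total_var)
}

new_similarity_matrix <- function(m, metric, subject_ids = NULL) {
  diag(m) <- NA_real_
  if (!is.null(subject_ids)) dimnames(m) <- list(subject_ids, subject_ids)
  structure(m, class = c("similarity_matrix", "matrix"), metric = metric)
}

#' Anna Karenina behavioral similarity matrix
#'
#' Scores are min-max normalized to \[0, 1\] over the analyzed sample
#' (or rank-normalized with `normalize = "rank"`), then
#' sim(i, j) = (s_i + s_j)/2 for `annak_mean` or min(s_i, s_j) for
#' `annak_min`. Both variants make high-trait pairs similar and low-trait
#' pairs dissimilar — the Anna Karenina structure in which all stressed
#' subjects respond alike while unstressed subjects are each idiosyncratic.
#'
#' @param scores per-subject trait scores (n >= 3, non-constant).
#' @param variant `"annak_mean"` (default) or `"annak_min"`.
#' @param normalize `"minmax"` (default) or `"rank"` (ranks scaled to \[0,1\]).
#' @param subject_ids optional ids for dimnames.
#' @return a `similarity_matrix` (symmetric, NA diagonal, values in \[0,1\]).
#' @export
annak_similarity <- function(scores, variant = c("annak_mean", "annak_min"),
                             normalize = c("minmax", "rank"),
                             subject_ids = NULL) {
  variant <- match.arg(variant)
  normalize <- match.arg(normalize)
  n <- length(scores)
  if (n < 3) stop_param("need at least 3 subjects")
  if (anyNA(scores)) stop_param("scores contain NA")
  if (min(scores) == max(scores))
    stop_param("constant scores: similarity normalization is undefined")
  s <- if (normalize == "minmax") minmax_norm(scores)
       else (rank(scores) - 1) / (n - 1)
  m <- if (variant == "annak_mean") outer(s, s, function(a, b) (a + b) / 2)
       else outer(s, s, pmin)
  new_similarity_matrix(m, variant, subject_ids)
}

#' Viewing-frequency similarity matrix
#'
#' [annak_similarity()] applied to self-reported viewing frequency (1..5).
#'
#' @inheritParams annak_similarity
#' @param freqs per-subject integer frequencies in 1..5.
#' @export
frequency_similarity <- function(freqs, variant = c("annak_mean", "annak_min"),
                                 subject_ids = NULL) {
  if (any(freqs < 1 | freqs > 5)) stop_param("frequencies must lie in 1..5")
  annak_similarity(freqs, variant = match.arg(variant),
                   subject_ids = subject_ids)
}

#' Descriptive summary of a behavioral table
#'
#' Mean, SD (n-1) and range for the stress composite and viewing frequency;
#' for each binary flag, the count, denominator and nearest-integer
#' percentage (100 * count / denominator).
#'
#' @param table behavioral data.frame with columns `item1..itemK`, `freq`,
#'   `willing`, and any number of `familiar_*` flags.
#' @param reverse_keys passed to [score_stress()].
#' @return list with `n`, `stress` (mean/sd/min/max/alpha), `freq`
#'   (mean/sd), and `flags`, a data.frame of count/denominator/percent per
#'   binary variable.
#' @export
describe_sample <- function(table, reverse_keys = integer(0)) {
  if (nrow(table) == 0L) stop_param("empty behavioral table")
  item_cols <- grep("^item[0-9]+$", names(table), value = TRUE)
  if (length(item_cols) < 2) stop_param("no item columns found")
  items <- validate_items(as.matrix(table[, item_cols]))
  composite <- score_stress(items, reverse_keys)
  flag_cols <- c("willing", grep("^familiar", names(table), value = TRUE))
  flag_cols <- intersect(flag_cols, names(table))
  flags <- do.call(rbind, lapply(flag_cols, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    data.frame(variable = v, count = sum(x[ok] == 1),
               denominator = sum(ok),
               percent = percent_int(sum(x[ok] == 1), sum(ok)),
               stringsAsFactors = FALSE)
  }))
  list(
    n = nrow(table),
    stress = list(mean = mean(composite), sd = stats::sd(composite),
                  min = min(composite), max = max(composite),
                  alpha = tryCatch(cronbach_alpha(items),
                                   error = function(e) NA_real_)),
    freq = if ("freq" %in% names(table))
      list(mean = mean(table$freq), sd = stats::sd(table$freq)) else NULL,
    flags = flags
  )
}
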