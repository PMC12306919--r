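# SubjectTimeseriesSet: the pipeline's central container. One ROI x time
# matrix per subject, all subjects sharing ROI set, run structure and length.

#' Construct a subject time-series set
#'
#' @param series named list, one ROI x time numeric matrix per subject; all
#'   matrices must share row (ROI) labels and column count.
#' @param runs data.frame with columns `name` and `length` partitioning the
#'   time axis into contiguous named segments (videos), in scan order.
#' @param tr repetition time in seconds (sampling interval).
#' @return object of class `subject_ts_set` with elements `series`, `runs`
#'   (with computed `start`), `tr`, `roi_labels`.
#' @export
subject_ts_set <- function(series, runs, tr = 1) {
  if (length(series) < 1L) stop_param("need at least one subject")
  if (is.null(names(series)) || anyDuplicated(names(series)))
    stop_param("series must be a named list with unique subject ids")
  ref <- series[[1L]]
  if (!is.matrix(ref) || is.null(rownames(ref)))
    stop_param("each subject's series must be an ROI x time matrix with ROI rownames")
  for (id in names(series)) {
    m <- series[[id]]
    if (!is.matrix(m) || !identical(dim(m), dim(ref)) ||
        !identical(rownames(m), rownames(ref)))
      stop_param("subject %s: ROI set or series length differs from the first subject", id)
    if (anyNA(m)) stop_param("subject %s: series contains NA", id)
  }
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  if (!all(c("name", "length") %in% names(runs)))
    stop_param("runs needs columns 'name' and 'length'")
  if (anyDuplicated(runs$name)) stop_param("run names must be unique")
  if (sum(runs$length) != ncol(ref))
    stop_param("run lengths sum to %d but series have %d time points",
               sum(runs$length), ncol(ref))
  runs$length <- as.integer(runs$length)
  runs$start <- cumsum(c(1L, runs$length[-nrow(runs)]))
  structure(list(series = series, runs = runs[, c("name", "start", "length")],
                 tr = tr, roi_labels = rownames(ref)),
            class = "subject_ts_set")
}

#' @export
print.subject_ts_set <- function(x, ...) {
  cat(sprintf("subject_ts_set: %d subjects x %d ROIs x %d time points (TR = %gs)\n",
              length(x$series), length(x$roi_labels),
              sum(x$runs$length), x$tr))
  cat("runs:", paste(sprintf("%s[%d]", x$runs$name, x$runs$length),
                     collapse = ", "), "\n")
  invisible(x)
}

run_indices <- function(set, segment) {
  i <- match(segment, set$runs$name)
  if (is.na(i)) stop_param("unknown run segment '%s'", segment)
  seq(set$runs$start[i], length.out = set$runs$length[i])
}

#' Extract a subjects x time matrix for one ROI and one segment
#'
#' @param set a [subject_ts_set()].
#' @param roi ROI label.
#' @param segments character vector of run names, or `NULL` for the full
#'   time axis.
#' @return numeric matrix, one row per subject.
#' @export
roi_matrix <- function(set, roi, segments = NULL) {
  stopifnot(inherits(set, "subject_ts_set"))
  if (!roi %in% set$roi_labels) stop_param("unknown ROI '%s'", roi)
  idx <- if (is.null(segments)) seq_len(sum(set$runs$length))
         else unlist(lapply(segments, run_indices, set = set))
  out <- t(vapply(set$series, function(m) m[roi, idx], numeric(length(idx))))
  rownames(out) <- names(set$series)
  out
}

#' Select and concatenate runs, optionally z-scoring each run first
#'
#' Joins the named segments in the given fixed order, identically for every
#' subject. With `per_run_standardize = TRUE` (default) each segment is
#' z-scored per subject and ROI before joining, so no single run dominates the
#' concatenated correlation through a variance difference.
#'
#' @param set a [subject_ts_set()].
#' @param segments run names to keep, in output order; default all runs.
#' @param per_run_standardize z-score each segment before joining.
#' @return a new [subject_ts_set()] containing only the requested segments.
#' @export
concatenate_runs <- function(set, segments = NULL, per_run_standardize = TRUE) {
  stopifnot(inherits(set, "subject_ts_set"))
  if (is.null(segments)) segments <- set$runs$name
  idx_list <- lapply(segments, run_indices, set = set)
  series <- lapply(set$series, function(m) {
    parts <- lapply(idx_list, function(idx) {
      x <- m[, idx, drop = FALSE]
      if (per_run_standardize) {
        mu <- rowMeans(x)
        sdv <- apply(x, 1L, stats::sd)
        if (any(sdv == 0))
          stop_param("cannot standardize a constant segment (ROI '%s')",
                     rownames(x)[which(sdv == 0)[1L]])
        x <- (x - mu) / sdv
      }
      x
    })
    do.call(cbind, parts)
  })
  runs <- data.frame(name = make.unique(segments),
                     length = vapply(idx_list, length, integer(1L)),
                     stringsAsFactors = FALSE)
  subject_ts_set(series, runs, tr = set$tr)
}
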