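# Synthetic data generator: subject x ROI x time ensembles with a known
# shared stimulus-locked signal, plus behavioral tables with a latent stress
# trait. Every dataset carries its ground truth so recovery and calibration
# tests can compare estimates against the generative parameters.

#' Configuration for the synthetic fMRI ensemble generator
#'
#' Describes a naturalistic viewing experiment: `n_subjects` participants each
#' scanned through the same ordered runs (videos), with `n_rois` regional time
#' series per subject sampled once per TR. Each region/run has a base shared
#' fraction \eqn{w_0 \in [0,1]}: the proportion of a subject's signal variance
#' carried by the run's common stimulus-locked time course. A subject's
#' effective weight is \eqn{w_i = \mathrm{clip}(w_0 + \beta \tilde s_i,\ 0,\ 0.95)}
#' where \eqn{\tilde s_i} is the subject's latent stress trait min-max
#' normalized to \[0, 1\] and \eqn{\beta \ge 0} (`annak_coupling`) is the
#' strength with which stress raises synchrony — the Anna Karenina structure
#' in which high-trait subjects resemble one another.
#'
#' Defaults mirror a 72-subject experiment with 16 ROIs and four ~3-minute
#' runs (three ASMR videos plus one control) at TR = 1 s; `interitem_corr =
#' 0.4` yields a 6-item stress scale with Spearman-Brown reliability near
#' 0.80; `annak_coupling = 0` means stress does not modulate synchrony.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param run_lengths integer vector of time points per run (each >= 3).
#' @param run_names names for the runs; defaults to `video1..3, control`.
#' @param n_rois number of regions.
#' @param base_shared_fraction either a single value in \[0,1\], or an
#'   `n_rois` x `n_runs` matrix of per-region, per-run shared fractions.
#' @param annak_coupling beta >= 0, stress-to-synchrony coupling.
#' @param ar1_coef AR(1) coefficient in \[0,1) applied to both the common
#'   signal and subject noise (fMRI-like temporal smoothness).
#' @param n_items number of stress questionnaire items.
#' @param interitem_corr target Pearson correlation between item columns,
#'   in \[0,1).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 72L,
                             run_lengths = c(180L, 180L, 180L, 180L),
                             run_names = NULL,
                             n_rois = 16L,
                             base_shared_fraction = 0.05,
                             annak_coupling = 0,
                             ar1_coef = 0.3,
                             n_items = 6L,
                             interitem_corr = 0.4,
                             seed = 1L) {
  if (n_subjects < 3) stop_param("n_subjects must be >= 3, got %s", n_subjects)
  if (any(run_lengths < 3)) stop_param("all run_lengths must be >= 3")
  if (n_rois < 1) stop_param("n_rois must be >= 1")
  n_runs <- length(run_lengths)
  if (is.null(run_names)) {
    run_names <- if (n_runs <= 4L)
      c("video1", "video2", "video3", "control")[seq_len(n_runs)]
    else paste0("run", seq_len(n_runs))
  }
  if (length(run_names) != n_runs || anyDuplicated(run_names))
    stop_param("run_names must be %d unique names", n_runs)
  w0 <- base_shared_fraction
  if (length(w0) == 1L) w0 <- matrix(w0, n_rois, n_runs)
  w0 <- as.matrix(w0)
  if (!all(dim(w0) == c(n_rois, n_runs)))
    stop_param("base_shared_fraction must be scalar or %d x %d", n_rois, n_runs)
  if (any(w0 < 0 | w0 > 1)) stop_param("shared fractions must lie in [0, 1]")
  if (annak_coupling < 0) stop_param("annak_coupling must be >= 0")
  if (ar1_coef < 0 || ar1_coef >= 1) stop_param("ar1_coef must be in [0, 1)")
  if (n_items < 2) stop_param("n_items must be >= 2")
  if (interitem_corr < 0 || interitem_corr >= 1)
    stop_param("interitem_corr must be in [0, 1), got %s", interitem_corr)
  dimnames(w0) <- list(NULL, run_names)
  structure(list(
    n_subjects = as.integer(n_subjects),
    run_lengths = as.integer(run_lengths),
    run_names = run_names,
    n_rois = as.integer(n_rois),
    base_shared_fraction = w0,
    annak_coupling = annak_coupling,
    ar1_coef = ar1_coef,
    n_items = as.integer(n_items),
    interitem_corr = interitem_corr,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Stationary AR(1) series with unit marginal variance, as columns of a matrix.
ar1_matrix <- function(n_t, n_series, a) {
  innov <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
  if (a == 0) return(innov)
  innov[-1L, ] <- innov[-1L, ] * sqrt(1 - a^2)
  apply(innov, 2L, function(e) as.numeric(stats::filter(e, a, method = "recursive")))
}

# First-Hermite attenuation factor of equal-probability discretization into
# `levels` categories: corr(categories) ~= factor * corr(latent).
likert_attenuation <- function(levels = 5L) {
  tau <- stats::qnorm(seq_len(levels - 1L) / levels)
  v <- mean(seq_len(levels)^2) - mean(seq_len(levels))^2
  sum(stats::dnorm(tau))^2 / v
}

#' Generate Likert stress questionnaire items with a latent trait
#'
#' Items are generated from a single-factor equicorrelated Gaussian model,
#' \eqn{y_{ik} = \sqrt{\rho}\, u_i + \sqrt{1-\rho}\, e_{ik}}, then discretized
#' at equal-probability normal cutpoints into the 1..5 Likert range. The
#' latent correlation \eqn{\rho} is inflated by the analytic discretization
#' attenuation factor so that the observed inter-item Pearson correlation
#' matches `interitem_corr`; the resulting Cronbach alpha then follows the
#' Spearman-Brown prophecy \eqn{\alpha \approx k\bar r/(1+(k-1)\bar r)}.
#'
#' @param n_subjects,n_items table dimensions (`n_items >= 2`).
#' @param interitem_corr target observed inter-item correlation in \[0,1).
#' @param seed integer seed.
#' @param levels number of Likert levels (default 5).
#' @return list with `items` (n_subjects x n_items integer matrix in
#'   1..levels) and `latent_stress` (the continuous trait \eqn{u_i}).
#' @export
generate_stress_items <- function(n_subjects, n_items = 6L, interitem_corr = 0.4,
                                  seed = 1L, levels = 5L) {
  if (n_items < 2) stop_param("n_items must be >= 2")
  if (interitem_corr < 0 || interitem_corr >= 1)
    stop_param("interitem_corr must be in [0, 1), got %s", interitem_corr)
  rho <- min(interitem_corr / likert_attenuation(levels), 0.999)
  cut <- stats::qnorm(seq_len(levels - 1L) / levels)
  with_seed(seed, {
    u <- stats::rnorm(n_subjects)
    e <- matrix(stats::rnorm(n_subjects * n_items), n_subjects, n_items)
    y <- sqrt(rho) * u + sqrt(1 - rho) * e
    items <- matrix(findInterval(y, cut) + 1L, n_subjects, n_items)
    colnames(items) <- paste0("item", seq_len(n_items))
    list(items = items, latent_stress = u)
  })
}

#' Expected pairwise correlation under the shared-signal model
#'
#' If subjects i and j carry shared-signal fractions \eqn{w_i, w_j} of a
#' common unit-variance time course, their expected Pearson correlation is
#' \eqn{\sqrt{w_i w_j}}. This closed form is the oracle used by the
#' parameter-recovery tests.
#'
#' @param w_i,w_j shared fractions in \[0,1\] (vectorized).
#' @return \eqn{\sqrt{w_i w_j}}.
#' @export
expected_pairwise_correlation <- function(w_i, w_j) {
  if (any(w_i < 0 | w_i > 1) || any(w_j < 0 | w_j > 1))
    stop_param("shared fractions must lie in [0, 1]")
  sqrt(w_i * w_j)
}

# Min-max normalize to [0,1]; a constant vector maps to the midpoint 0.5
# (so annak_coupling contributes its half-range rather than being undefined).
minmax_norm <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Generate a subject x ROI x time ensemble with known ground truth
#'
#' Each subject's series in region v, run r is
#' \eqn{x(t) = \sqrt{w_i}\, c(t) + \sqrt{1-w_i}\, \epsilon_i(t)} with a
#' common signal \eqn{c} shared by all subjects and idiosyncratic noise
#' \eqn{\epsilon_i}, both stationary unit-variance AR(1) processes. The
#' effective weight is \eqn{w_i = \mathrm{clip}(w_0 + \beta \tilde s_i, 0, 0.95)};
#' the ceiling 0.95 avoids degenerate r = 1 pairs that break the Fisher z
#' transform. Expected pairwise correlation is \eqn{\sqrt{w_i w_j}}.
#'
#' @param config a [synthetic_config()].
#' @param latent_stress per-subject latent trait; if `NULL`, drawn internally
#'   from the questionnaire model so behavioral and neural data share one trait.
#' @return list with `data` (a [subject_ts_set()]) and `truth`, a list holding
#'   `latent_stress`, `effective_weight` (subjects x ROIs x runs) and
#'   `common_signals` (ROIs x time).
#' @export
generate_timeseries <- function(config, latent_stress = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  if (is.null(latent_stress)) {
    latent_stress <- generate_stress_items(
      n, config$n_items, config$interitem_corr,
      seed = derive_seed(config$seed, 1L))$latent_stress
  }
  if (length(latent_stress) != n)
    stop_param("latent_stress must have length n_subjects = %d", n)
  s_norm <- minmax_norm(latent_stress)
  n_runs <- length(config$run_lengths)
  total_t <- sum(config$run_lengths)
  run_end <- cumsum(config$run_lengths)
  run_start <- run_end - config$run_lengths + 1L
  roi_labels <- paste0("roi", seq_len(config$n_rois))

  # effective weight per subject x roi x run
  w <- array(0, dim = c(n, config$n_rois, n_runs),
             dimnames = list(NULL, roi_labels, config$run_names))
  for (r in seq_len(n_runs))
    w[, , r] <- pmin(pmax(
      matrix(config$base_shared_fraction[, r], n, config$n_rois, byrow = TRUE) +
        config$annak_coupling * s_norm, 0), 0.95)

  with_seed(derive_seed(config$seed, 2L), {
    # common stimulus-locked signals: one series per ROI per run
    common <- matrix(0, config$n_rois, total_t)
    for (r in seq_len(n_runs)) {
      idx <- run_start[r]:run_end[r]
      common[, idx] <- t(ar1_matrix(config$run_lengths[r], config$n_rois,
                                    config$ar1_coef))
    }
    series <- vector("list", n)
    for (i in seq_len(n)) {
      x <- matrix(0, config$n_rois, total_t)
      for (r in seq_len(n_runs)) {
        idx <- run_start[r]:run_end[r]
        eps <- t(ar1_matrix(config$run_lengths[r], config$n_rois, config$ar1_coef))
        wi <- w[i, , r]
        x[, idx] <- sqrt(wi) * common[, idx] + sqrt(1 - wi) * eps
      }
      rownames(x) <- roi_labels
      series[[i]] <- x
    }
    ids <- sprintf("sub-%03d", seq_len(n))
    names(series) <- ids
    data <- subject_ts_set(series,
                           runs = data.frame(name = config$run_names,
                                             length = config$run_lengths,
                                             stringsAsFactors = FALSE),
                           tr = 1)
    rownames(common) <- roi_labels
    list(data = data,
         truth = list(latent_stress = latent_stress,
                      normalized_stress = s_norm,
                      effective_weight = w,
                      common_signals = common,
                      config = config))
  })
}

#' Generate a complete synthetic dataset (neural + behavioral)
#'
#' Draws the questionnaire items first, then reuses the same latent stress
#' trait to drive the neural generator, so the Anna Karenina coupling links
#' the two. The post-experiment variables emulate typical self-report
#' distributions: low viewing frequency (mean near 1.6 on 1..5), familiarity
#' rates of roughly 71/11/5 percent for the three channels, and an even
#' willingness split.
#'
#' @param config a [synthetic_config()].
#' @return list with `data`, `behavioral` (data.frame), `truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  st <- generate_stress_items(n, config$n_items, config$interitem_corr,
                              seed = derive_seed(config$seed, 1L))
  gen <- generate_timeseries(config, latent_stress = st$latent_stress)
  behav <- with_seed(derive_seed(config$seed, 3L), {
    data.frame(
      subject_id = names(gen$data$series),
      st$items,
      freq = sample(1:5, n, replace = TRUE,
                    prob = c(0.70, 0.15, 0.08, 0.04, 0.03)),
      willing = stats::rbinom(n, 1L, 0.5),
      familiar_ch1 = stats::rbinom(n, 1L, 0.71),
      familiar_ch2 = stats::rbinom(n, 1L, 0.11),
      familiar_ch3 = stats::rbinom(n, 1L, 0.05),
      stringsAsFactors = FALSE
    )
  })
  list(data = gen$data, behavioral = behav, truth = gen$truth)
}

#' Write a synthetic dataset to a fixture directory
#'
#' Writes one tab-delimited time-series file per subject (rows = time points,
#' columns = ROI labels, header mandatory), the behavioral CSV, the ground
#' truth as JSON, and a manifest recording the seed, configuration and a
#' checksum. All content is validated before the first byte is written, and
#' files are written to a staging directory and renamed in, so a failure
#' leaves no partial fixture.
#'
#' @param dataset a [subject_ts_set()].
#' @param behavioral behavioral data.frame (as from [generate_dataset()]).
#' @param truth ground-truth list (may be `NULL` for real data).
#' @param directory target directory; must already exist.
#' @param digits significant digits stored for the series (default 6).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
write_fixture <- function(dataset, behavioral, truth, directory, digits = 6L) {
  stopifnot(inherits(dataset, "subject_ts_set"))
  if (!dir.exists(directory))
    stop_param("fixture directory does not exist: %s", directory)
  if (!identical(behavioral$subject_id, names(dataset$series)))
    stop_param("behavioral subject_id column must match the time-series subjects")
  stage <- file.path(directory, ".staging")
  dir.create(stage, showWarnings = FALSE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  ts_files <- sprintf("%s_timeseries.tsv", names(dataset$series))
  for (i in seq_along(dataset$series)) {
    m <- signif(t(dataset$series[[i]]), digits)  # time x ROI
    utils::write.table(m, file.path(stage, ts_files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(behavioral, file.path(stage, "behavioral.csv"),
                   row.names = FALSE)
  runs_df <- dataset$runs
  config <- if (!is.null(truth)) truth$config else NULL
  if (!is.null(truth)) {
    tr_out <- truth
    tr_out$config <- NULL
    jsonlite::write_json(tr_out, file.path(stage, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  cfg_json <- if (!is.null(config)) {
    jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  } else NULL
  cfg_file <- file.path(stage, "config.json")
  if (!is.null(cfg_json)) writeLines(as.character(cfg_json), cfg_file)
  manifest <- list(
    format = "iscrsa-fixture-1",
    n_subjects = length(dataset$series),
    n_rois = nrow(dataset$series[[1L]]),
    runs = runs_df,
    tr = dataset$tr,
    timeseries_files = ts_files,
    behavioral_file = "behavioral.csv",
    ground_truth_file = if (!is.null(truth)) "ground_truth.json" else NULL,
    seed = if (!is.null(config)) config$seed else NULL,
    config_md5 = if (!is.null(cfg_json)) unname(tools::md5sum(cfg_file)) else NULL
  )
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  for (f in list.files(stage)) {
    ok <- file.rename(file.path(stage, f), file.path(directory, f))
    if (!ok) stop_param("failed to move fixture file %s into place", f)
  }
  invisible(manifest)
}
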