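# Config-driven orchestration: simulate or load a dataset, run the full
# ISC / IS-RSA battery, and emit report tables with seeds and provenance.

#' Analysis configuration
#'
#' @param input `"synthetic"` or `"files"`.
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param data_dir fixture directory written by [write_fixture()] (file mode).
#' @param video_segments run names of the experimental (ASMR) videos.
#' @param control_segment run name of the control video, or `NULL`.
#' @param reverse_keys reverse-keyed stress items (default none).
#' @param annak_variant `"annak_mean"` (default) or `"annak_min"`.
#' @param n_bootstrap subject-wise bootstrap iterations (default 5000).
#' @param n_permutations Mantel / group permutations (default 5000).
#' @param alpha significance level for post-hoc selection (default 0.05).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir if non-`NULL`, report tables are written there as TSV.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input = c("synthetic", "files"),
                            synthetic = synthetic_config(),
                            data_dir = NULL,
                            video_segments = c("video1", "video2", "video3"),
                            control_segment = "control",
                            reverse_keys = integer(0),
                            annak_variant = "annak_mean",
                            n_bootstrap = 5000L,
                            n_permutations = 5000L,
                            alpha = 0.05,
                            seed = 1L,
                            out_dir = NULL) {
  input <- match.arg(input)
  if (input == "files") {
    if (is.null(data_dir) || !dir.exists(data_dir))
      stop_param("file mode requires an existing data_dir")
  }
  if (alpha <= 0 || alpha >= 1) stop_param("alpha must be in (0, 1)")
  if (n_bootstrap < 100 || n_permutations < 100)
    stop_param("n_bootstrap and n_permutations must be >= 100")
  structure(list(input = input, synthetic = synthetic, data_dir = data_dir,
                 video_segments = video_segments,
                 control_segment = control_segment,
                 reverse_keys = reverse_keys,
                 annak_variant = annak_variant,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read a fixture directory back into memory
#'
#' Counterpart of [write_fixture()]: reads the manifest, per-subject TSV time
#' series, behavioral CSV and (if present) the ground-truth JSON.
#'
#' @param directory fixture directory containing `manifest.json`.
#' @return list with `data` (a [subject_ts_set()]), `behavioral`, `truth`
#'   (or `NULL`), `manifest`.
#' @export
read_fixture <- function(directory) {
  mf_path <- file.path(directory, "manifest.json")
  if (!file.exists(mf_path)) stop_param("no manifest.json in %s", directory)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  runs <- as.data.frame(manifest$runs, stringsAsFactors = FALSE)
  series <- lapply(manifest$timeseries_files, function(f) {
    m <- as.matrix(utils::read.delim(file.path(directory, f),
                                     check.names = FALSE))
    t(m)  # stored time x ROI; container wants ROI x time
  })
  ids <- sub("_timeseries\\.tsv$", "", manifest$timeseries_files)
  names(series) <- ids
  behavioral <- utils::read.csv(file.path(directory, manifest$behavioral_file),
                                stringsAsFactors = FALSE)
  truth <- NULL
  if (!is.null(manifest$ground_truth_file) &&
      file.exists(file.path(directory, manifest$ground_truth_file)))
    truth <- jsonlite::read_json(file.path(directory, manifest$ground_truth_file),
                                 simplifyVector = TRUE)
  list(data = subject_ts_set(series, runs[, c("name", "length")],
                             tr = manifest$tr %||% 1),
       behavioral = behavioral, truth = truth, manifest = manifest)
}

#' Validate a fixture directory, reporting every problem found
#'
#' Checks file presence, run-length alignment across subjects, ROI-set
#' consistency, item ranges, and subject-id agreement between neural and
#' behavioral files. Never stops at the first problem.
#'
#' @param directory fixture directory.
#' @return character vector of problem descriptions (empty when valid).
#' @export
validate_inputs <- function(directory) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  mf_path <- file.path(directory, "manifest.json")
  if (!file.exists(mf_path)) {
    return(sprintf("missing manifest.json in %s", directory))
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  expected_t <- sum(manifest$runs$length)
  shapes <- list(); ids <- character(0)
  for (f in manifest$timeseries_files) {
    p <- file.path(directory, f)
    if (!file.exists(p)) { note("missing time-series file %s", f); next }
    m <- utils::read.delim(p, check.names = FALSE)
    id <- sub("_timeseries\\.tsv$", "", f)
    ids <- c(ids, id)
    shapes[[id]] <- dim(m)
    if (nrow(m) != expected_t)
      note("subject %s: %d time points, runs define %d", id, nrow(m), expected_t)
    if (anyNA(m)) note("subject %s: series contains NA", id)
  }
  n_roi <- vapply(shapes, `[`, integer(1L), 2L)
  if (length(unique(n_roi)) > 1)
    note("inconsistent ROI counts across subjects: %s",
         paste(unique(n_roi), collapse = ", "))
  bpath <- file.path(directory, manifest$behavioral_file %||% "behavioral.csv")
  if (!file.exists(bpath)) {
    note("missing behavioral file %s", basename(bpath))
  } else {
    behav <- utils::read.csv(bpath, stringsAsFactors = FALSE)
    miss <- setdiff(ids, behav$subject_id)
    extra <- setdiff(behav$subject_id, ids)
    for (s in miss) note("subject %s has time series but no behavioral row", s)
    for (s in extra) note("subject %s has behavioral row but no time series", s)
    item_cols <- grep("^item[0-9]+$", names(behav), value = TRUE)
    if (length(item_cols) < 2) note("behavioral file has no item columns")
    else {
      it <- as.matrix(behav[, item_cols])
      if (anyNA(it) || any(it < 1 | it > 5))
        note("behavioral items outside 1..5 or missing")
    }
  }
  problems
}

#' Simulate a dataset and write it as a fixture directory
#'
#' @param config a [synthetic_config()].
#' @param directory existing target directory.
#' @return invisibly, the manifest (see [write_fixture()]).
#' @export
simulate_fixture <- function(config, directory) {
  ds <- generate_dataset(config)
  write_fixture(ds$data, ds$behavioral, ds$truth, directory)
}

#' Run the full ISC / IS-RSA analysis battery
#'
#' Executes, in order: data simulation or loading; per-video pairwise ISC for
#' every ROI; Friedman omnibus across videos per ROI with BH-FDR across
#' ROIs, and Wilcoxon post hocs (BH within the significant-ROI x video-pair
#' family) where the omnibus q falls below `alpha`; ISC on run-standardized
#' concatenated video series with subject-wise bootstrap and BH-FDR; IS-RSA
#' (stress Anna Karenina similarity) per video, concatenated and control
#' condition with Mantel permutation inference and per-condition BH-FDR;
#' paired-t contrasts of each video's IS-RSA profile against the control;
#' group ISC differences for the willingness and familiarity splits (skipped
#' with a note when a group has fewer than 3 subjects); viewing-frequency
#' IS-RSA; and the behavioral summary. Deterministic given config + seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle` with elements `isc_table`,
#'   `friedman_table`, `posthoc_table`, `isrsa_table`, `contrast_table`,
#'   `group_table`, `frequency_isrsa_table`, `behavioral_summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed

  ## 1. data
  if (config$input == "synthetic") {
    cfg <- config$synthetic
    cfg$seed <- derive_seed(seed, 10L)
    ds <- generate_dataset(cfg)
  } else {
    ds <- read_fixture(config$data_dir)
  }
  set <- ds$data
  behav <- ds$behavioral
  videos <- config$video_segments
  if (!all(videos %in% set$runs$name))
    stop_param("stage data: video segments %s not all present",
               paste(videos, collapse = ", "))

  ## 2. per-video ISC matrices
  per_video <- lapply(videos, function(v) isc_by_roi(set, v, condition = v))
  names(per_video) <- videos
  rois <- set$roi_labels

  ## 3. Friedman across videos + Wilcoxon post hocs
  friedman_table <- do.call(rbind, lapply(rois, function(roi) {
    ft <- friedman_across_conditions(lapply(per_video, `[[`, roi))
    data.frame(roi = roi, chi2 = ft$chi2, df = ft$df, p = ft$p,
               n_pairs = ft$n_pairs, stringsAsFactors = FALSE)
  }))
  friedman_table$q <- bh_fdr(friedman_table$p)
  sig_rois <- friedman_table$roi[friedman_table$q < config$alpha]
  posthoc_table <- NULL
  if (length(sig_rois)) {
    pairs <- utils::combn(videos, 2L, simplify = FALSE)
    posthoc_table <- do.call(rbind, lapply(sig_rois, function(roi) {
      do.call(rbind, lapply(pairs, function(pr) {
        w <- wilcoxon_signed_rank(upper_tri_values(per_video[[pr[1]]][[roi]]),
                                  upper_tri_values(per_video[[pr[2]]][[roi]]))
        data.frame(roi = roi, video_a = pr[1], video_b = pr[2],
                   W = w$W, z = w$z, p = w$p, stringsAsFactors = FALSE)
      }))
    }))
    posthoc_table$q <- bh_fdr(posthoc_table$p)
  }

  ## 4. concatenated ISC + bootstrap
  concat <- concatenate_runs(set, videos, per_run_standardize = TRUE)
  concat_mats <- isc_by_roi(concat, NULL, condition = "concatenated")
  isc_table <- do.call(rbind, lapply(seq_along(rois), function(i) {
    bt <- bootstrap_isc_test(concat_mats[[i]], config$n_bootstrap,
                             seed = derive_seed(seed, 100L + i %% 100L))
    data.frame(roi = rois[i], isc = bt$observed, p = bt$p,
               n_iterations = bt$n_iterations, seed = bt$seed,
               stringsAsFactors = FALSE)
  }))
  isc_table$q <- bh_fdr(isc_table$p)

  ## 5. stress IS-RSA per video + concatenated + control
  stress <- score_stress(as.matrix(behav[, grep("^item[0-9]+$", names(behav))]),
                         config$reverse_keys)
  stress_sim <- annak_similarity(stress, variant = config$annak_variant,
                                 subject_ids = behav$subject_id)
  neural_conditions <- c(per_video, list(concatenated = concat_mats))
  has_control <- !is.null(config$control_segment) &&
    config$control_segment %in% set$runs$name
  if (has_control) {
    control_mats <- isc_by_roi(set, config$control_segment,
                               condition = config$control_segment)
    neural_conditions[[config$control_segment]] <- control_mats
  }
  isrsa_table <- isrsa_battery(neural_conditions, stress_sim,
                               n_permutations = config$n_permutations,
                               seed = derive_seed(seed, 200L))

  ## 6. paired-t contrasts of IS-RSA profiles: each video vs control
  contrast_table <- NULL
  if (has_control) {
    prof <- function(cond) isrsa_table$rho[isrsa_table$condition == cond]
    contrast_table <- do.call(rbind, lapply(videos, function(v) {
      ct <- paired_t_profile(prof(v), prof(config$control_segment))
      data.frame(condition = v, control = config$control_segment,
                 t = ct$t, df = ct$df, p = ct$p, mean_diff = ct$mean_diff,
                 stringsAsFactors = FALSE)
    }))
  }

  ## 7. group ISC comparisons (willingness, familiarity)
  group_vars <- intersect(c("willing", grep("^familiar", names(behav),
                                            value = TRUE)), names(behav))
  group_rows <- list(); group_notes <- character(0)
  for (gi in seq_along(group_vars)) {
    gv <- group_vars[gi]
    lab <- behav[[gv]]
    if (sum(lab == 1) < 3 || sum(lab == 0) < 3) {
      group_notes <- c(group_notes, sprintf(
        "%s: group sizes %d/%d too small for within-group ISC; skipped",
        gv, sum(lab == 1), sum(lab == 0)))
      next
    }
    g <- group_isc_difference(concat, lab, NULL,
                              n_permutations = config$n_permutations,
                              seed = derive_seed(seed, 300L + gi))
    g$q <- bh_fdr(g$p)
    g$variable <- gv
    group_rows[[gv]] <- g
  }
  group_table <- if (length(group_rows)) do.call(rbind, group_rows) else NULL

  ## 8. viewing-frequency IS-RSA (concatenated)
  frequency_isrsa_table <- NULL
  if ("freq" %in% names(behav) && min(behav$freq) != max(behav$freq)) {
    freq_sim <- frequency_similarity(behav$freq, config$annak_variant,
                                     subject_ids = behav$subject_id)
    frequency_isrsa_table <- isrsa_battery(
      list(concatenated = concat_mats), freq_sim,
      n_permutations = config$n_permutations,
      seed = derive_seed(seed, 400L))
  }

  ## 9. behavioral summary + manifest
  behavioral_summary <- describe_sample(behav, config$reverse_keys)
  manifest <- list(
    package_version = as.character(utils::packageVersion("iscrsa")),
    seed = seed, n_bootstrap = config$n_bootstrap,
    n_permutations = config$n_permutations, alpha = config$alpha,
    input = config$input, n_subjects = length(set$series),
    rois = rois, videos = videos,
    control = if (has_control) config$control_segment else NULL,
    group_notes = group_notes,
    timestamp = NULL  # kept NULL so identical configs give identical bundles
  )
  bundle <- structure(list(
    isc_table = isc_table, friedman_table = friedman_table,
    posthoc_table = posthoc_table, isrsa_table = isrsa_table,
    contrast_table = contrast_table, group_table = group_table,
    frequency_isrsa_table = frequency_isrsa_table,
    behavioral_summary = behavioral_summary, manifest = manifest
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle as TSV tables plus a JSON manifest
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param directory existing output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(bundle, directory) {
  if (!dir.exists(directory)) stop_param("output directory does not exist: %s",
                                         directory)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(directory, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(bundle$isc_table, "isc_concatenated")
  wt(bundle$friedman_table, "friedman_across_videos")
  wt(bundle$posthoc_table, "wilcoxon_posthoc")
  wt(bundle$isrsa_table, "isrsa")
  wt(bundle$contrast_table, "isrsa_contrasts")
  wt(bundle$group_table, "group_isc")
  wt(bundle$frequency_isrsa_table, "frequency_isrsa")
  jsonlite::write_json(bundle$behavioral_summary,
                       file.path(directory, "behavioral_summary.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(directory, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(directory)
}
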