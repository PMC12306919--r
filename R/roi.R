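# Spherical ROI definition at MNI millimeter coordinates, voxel mask
# construction on an arbitrary grid, and reduction of 4D volumes to
# ROI x time matrices.

#' Load an ROI table from CSV
#'
#' Expects columns `label`, `x`, `y`, `z` (MNI mm) and optionally `diameter`
#' (mm, default 6) and `source_note`. Lines starting with `#` are comments.
#' Labels must be unique.
#'
#' @param path CSV file path.
#' @param default_diameter sphere diameter used when the column is absent.
#' @return data.frame of class `roi_table` with columns `label`, `x`, `y`,
#'   `z`, `diameter`, `source_note`.
#' @export
load_roi_table <- function(path, default_diameter = 6) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_param("ROI table needs columns %s", paste(need, collapse = ", "))
  for (v in c("x", "y", "z")) {
    if (!is.numeric(df[[v]]))
      stop_param("non-numeric coordinates in column '%s'", v)
    df[[v]] <- as.numeric(df[[v]])
  }
  dup <- df$label[duplicated(df$label)]
  if (length(dup))
    stop_param("duplicate ROI label(s): %s", paste(unique(dup), collapse = ", "))
  if (!"diameter" %in% names(df)) df$diameter <- default_diameter
  if (any(df$diameter <= 0)) stop_param("diameters must be > 0")
  if (!"source_note" %in% names(df)) df$source_note <- ""
  df <- df[, c("label", "x", "y", "z", "diameter", "source_note")]
  class(df) <- c("roi_table", "data.frame")
  df
}

#' Path to the bundled 16-ROI stress table
#'
#' Sixteen 6-mm spheres at MNI coordinates covering bilateral insula, basal
#' ganglia and amygdala plus left frontal, parietal, thalamic and
#' parahippocampal regions commonly implicated in stress processing.
#' Coordinates are stored exactly as published (see the comments inside the
#' file for two internally inconsistent entries kept as printed); repeated
#' region names carry a numeric suffix to keep labels unique.
#'
#' @return file path of the CSV shipped with the package.
#' @export
stress_roi_table_path <- function() {
  system.file("extdata", "stress_rois_16.csv", package = "iscrsa",
              mustWork = TRUE)
}

#' Define a sampling grid (voxel lattice with an affine)
#'
#' The affine is the authoritative voxel-index -> MNI mm mapping (NIfTI
#' convention, 0-based voxel indices): `mm = affine %*% c(i, j, k, 1)`.
#'
#' @param dims integer 3-vector of grid dimensions.
#' @param affine 4x4 numeric matrix; must be invertible.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(dims, affine) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1)) stop_param("dims must be 3 positive counts")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_param("affine must be 4x4")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop_param("affine is not invertible")
  structure(list(dims = dims, affine = affine), class = "grid_spec")
}

#' Convenience constructor for an axis-aligned grid
#'
#' @param dims integer 3-vector.
#' @param voxel_size 3-vector of voxel edge lengths in mm (scalar recycled).
#' @param origin mm coordinate of voxel (0, 0, 0).
#' @return a [grid_spec()].
#' @export
grid_spec_axial <- function(dims, voxel_size = 2, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(voxel_size, 3L)
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- origin
  grid_spec(dims, affine)
}

#' Build a spherical voxel mask around an MNI coordinate
#'
#' Includes every voxel whose center lies at Euclidean distance <= radius
#' from `center_mm` (inclusive boundary). A 6-mm *diameter* sphere therefore
#' uses `radius_mm = 3`.
#'
#' @param center_mm MNI coordinate (mm), length 3.
#' @param radius_mm sphere radius in mm (> 0).
#' @param grid a [grid_spec()].
#' @return object of class `voxel_mask`: integer matrix of 0-based voxel
#'   indices (one row per voxel, columns i, j, k) with the grid attached.
#' @export
build_sphere_mask <- function(center_mm, radius_mm, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (radius_mm <= 0) stop_param("radius must be > 0")
  if (length(center_mm) != 3L) stop_param("center_mm must have length 3")
  inv <- solve(grid$affine)
  c_vox <- (inv %*% c(center_mm, 1))[1:3]
  # candidate bounding box in voxel units (radius / smallest voxel step)
  step <- apply(grid$affine[1:3, 1:3], 2L, function(col) sqrt(sum(col^2)))
  lo <- pmax(floor(c_vox - radius_mm / step) - 1, 0)
  hi <- pmin(ceiling(c_vox + radius_mm / step) + 1, grid$dims - 1)
  if (any(lo > hi))
    stop_param("sphere center maps outside the grid bounding box")
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- cand %*% t(grid$affine[1:3, 1:3])
  mm <- sweep(mm, 2L, grid$affine[1:3, 4], "+")
  d2 <- rowSums(sweep(mm, 2L, center_mm)^2)
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep))
    stop_param("empty mask: no voxel center within %g mm of (%s)",
               radius_mm, paste(center_mm, collapse = ", "))
  m <- cand[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  structure(m, class = c("voxel_mask", "matrix"), grid = grid)
}

#' Reduce a 4D volume to an ROI time series
#'
#' The ROI value at each time point is the unweighted mean over the mask
#' voxels. A time point whose mask voxels are all NaN yields NaN with a
#' warning; any NaN voxel propagates (no silent na.rm).
#'
#' @param volume4d 4D numeric array (i, j, k, t) on the mask's grid.
#' @param mask a [build_sphere_mask()] result.
#' @return numeric vector of length t.
#' @export
extract_timeseries <- function(volume4d, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  grid <- attr(mask, "grid")
  dv <- dim(volume4d)
  if (length(dv) != 4L) stop_param("volume must be 4D (i, j, k, t)")
  if (!all(dv[1:3] == grid$dims))
    stop_param("volume grid %s does not match mask grid %s",
               paste(dv[1:3], collapse = "x"),
               paste(grid$dims, collapse = "x"))
  n_t <- dv[4L]
  vol2d <- matrix(volume4d, prod(dv[1:3]), n_t)
  lin <- 1L + mask[, 1L] + dv[1L] * (mask[, 2L] + dv[2L] * mask[, 3L])
  vals <- vol2d[lin, , drop = FALSE]
  out <- colMeans(vals)
  all_nan <- apply(vals, 2L, function(v) all(is.nan(v)))
  if (any(all_nan))
    warning(sprintf("%d time point(s) have all-NaN mask voxels", sum(all_nan)))
  out
}

#' Extract ROI x time matrices for every subject from 4D volumes
#'
#' @param volumes named list of 4D arrays (or NIfTI file paths, read with
#'   RNifti), one per subject, all on `grid`.
#' @param roi_table a [load_roi_table()] result.
#' @param grid a [grid_spec()]; if `NULL` and inputs are NIfTI paths, the
#'   grid is taken from the first image's header.
#' @param runs run definition data.frame (`name`, `length`).
#' @param tr repetition time in seconds.
#' @return a [subject_ts_set()].
#' @export
extract_roi_set <- function(volumes, roi_table, grid = NULL, runs, tr = 1) {
  stopifnot(inherits(roi_table, "roi_table"))
  load_vol <- function(v) {
    if (is.character(v)) {
      img <- RNifti::readNifti(v)
      if (is.null(grid))
        grid <<- grid_spec(dim(img)[1:3], structure(RNifti::xform(img),
                                                    dim = c(4, 4)))
      unclass(img)
    } else v
  }
  vols <- lapply(volumes, load_vol)
  if (is.null(grid)) stop_param("grid must be given for in-memory arrays")
  masks <- lapply(seq_len(nrow(roi_table)), function(i)
    build_sphere_mask(c(roi_table$x[i], roi_table$y[i], roi_table$z[i]),
                      roi_table$diameter[i] / 2, grid))
  series <- lapply(vols, function(v) {
    m <- t(vapply(masks, function(msk) extract_timeseries(v, msk),
                  numeric(dim(v)[4L])))
    rownames(m) <- roi_table$label
    m
  })
  subject_ts_set(series, runs, tr = tr)
}

#' Export a voxel mask as a binary NIfTI map
#'
#' @param mask a [build_sphere_mask()] result.
#' @param path output `.nii` / `.nii.gz` path.
#' @return invisibly, the path.
#' @export
write_mask_nifti <- function(mask, path) {
  grid <- attr(mask, "grid")
  arr <- array(0L, dim = grid$dims)
  arr[mask + 1L] <- 1L
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
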