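#' Multi-voxel pattern set
#'
#' Samples x features response matrix with condition labels and per-sample
#' run identifiers. Features are either voxels (rows of the originating
#' dataset) or clusters.
#'
#' @param x numeric matrix, samples x features.
#' @param labels integer condition label per sample.
#' @param runs run identifier per sample.
#' @param feature_kind `"voxel"` or `"cluster"`.
#' @param feature_map feature index -> voxel row index or cluster id.
#' @return an object of class `mic_patterns`.
#' @export
mic_patterns <- function(x, labels, runs, feature_kind = "voxel",
                         feature_map = seq_len(ncol(x))) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(runs),
            ncol(x) == length(feature_map),
            !anyDuplicated(feature_map))
  structure(list(x = x, labels = labels, runs = runs,
                 feature_kind = feature_kind, feature_map = feature_map),
            class = "mic_patterns")
}

#' @export
print.mic_patterns <- function(x, ...) {
  cat(sprintf("Pattern set: %d samples x %d %s features (%d conditions)\n",
              nrow(x$x), ncol(x$x), x$feature_kind,
              length(unique(x$labels))))
  invisible(x)
}

#' Extract block-averaged multi-voxel patterns
#'
#' Converts a time series into one sample per stimulus block: the time
#' series is shifted by `shift_volumes` volumes (6 s at TR 2 s by default)
#' to account for the hemodynamic delay, and the signal of each voxel is
#' averaged over the volumes of each block. Shifted windows are truncated at
#' the end of their run — volumes are never borrowed across runs.
#'
#' @param ds a [mic_dataset()].
#' @param design a `mic_design` aligned with the dataset's volumes.
#' @param shift_volumes hemodynamic shift in volumes (default 3).
#' @return a [mic_patterns()] with voxel features, one sample per stimulus
#'   block, labeled by the block's condition.
#' @export
extract_patterns <- function(ds, design, shift_volumes = 3L) {
  if (shift_volumes < 0L) stop("'shift_volumes' must be non-negative")
  if (nrow(design) != ncol(ds$values))
    stop("design and dataset disagree on the number of volumes")
  samples <- list(); labels <- integer(); runs <- integer()
  truncated <- FALSE
  for (r in unique(design$run)) {
    vols_r <- which(design$run == r)
    cond_r <- design$condition[vols_r]
    rl <- rle(cond_r)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (b in which(rl$values > 0L)) {
      shifted <- starts[b]:ends[b] + shift_volumes
      kept <- shifted[shifted <= length(vols_r)]
      if (length(kept) < length(shifted)) truncated <- TRUE
      if (length(kept) == 0L) next
      samples[[length(samples) + 1L]] <-
        rowMeans(ds$values[, vols_r[kept], drop = FALSE])
      labels <- c(labels, rl$values[b])
      runs <- c(runs, r)
    }
  }
  if (truncated)
    warning("shifted block(s) extended past the end of a run; truncated")
  mic_patterns(do.call(rbind, samples), labels, runs, "voxel",
               seq_len(nrow(ds$values)))
}

#' Linear detrending within runs
#'
#' Removes, per voxel and per run, the least-squares line over volume index.
#' Runs are processed independently, so between-run structure outside the
#' linear trend is untouched.
#'
#' @param ds a [mic_dataset()].
#' @return the detrended `mic_dataset`.
#' @export
detrend_linear <- function(ds) {
  values <- ds$values
  for (r in unique(ds$run_ids)) {
    vols <- which(ds$run_ids == r)
    if (length(vols) < 2L)
      stop("linear detrending requires at least 2 volumes per run")
    X <- cbind(1, seq_along(vols))
    Q <- qr.Q(qr(X))
    V <- values[, vols, drop = FALSE]
    values[, vols] <- V - (V %*% Q) %*% t(Q)
  }
  mic_dataset(values, ds$voxel_coords, ds$voxel_dims, ds$tr_seconds,
              ds$run_ids, ds$mask_shape)
}

#' Spatial Gaussian smoothing within the mask
#'
#' Smooths each volume with a separable Gaussian kernel of the given FWHM.
#' Smoothing is mask-normalized: the masked values and the mask indicator
#' are smoothed with the same kernel and divided, so no zeros leak in from
#' outside the mask and spatially constant data are left unchanged.
#'
#' @param ds a [mic_dataset()].
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return the smoothed `mic_dataset`.
#' @export
gaussian_smooth <- function(ds, fwhm_mm) {
  if (fwhm_mm <= 0) stop("'fwhm_mm' must be positive")
  shape <- ds$mask_shape
  lin <- voxel_linear_index(ds$voxel_coords, shape)
  full <- matrix(0, prod(shape), ncol(ds$values))
  full[lin, ] <- ds$values
  mask <- matrix(0, prod(shape), 1L)
  mask[lin, 1L] <- 1
  num <- smooth_field(full, shape, ds$voxel_dims, fwhm_mm)
  den <- smooth_field(mask, shape, ds$voxel_dims, fwhm_mm)
  values <- num[lin, , drop = FALSE] / den[lin, 1L]
  mic_dataset(values, ds$voxel_coords, ds$voxel_dims, ds$tr_seconds,
              ds$run_ids, ds$mask_shape)
}

#' Split a pattern set by sample index
#'
#' @param patterns a [mic_patterns()].
#' @param samples sample indices to keep.
#' @return the restricted `mic_patterns`.
#' @export
subset_patterns <- function(patterns, samples) {
  mic_patterns(patterns$x[samples, , drop = FALSE],
               patterns$labels[samples], patterns$runs[samples],
               patterns$feature_kind, patterns$feature_map)
}
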