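#' Masked BOLD time-series dataset
#'
#' The central data container: the time series of every in-mask voxel,
#' together with the voxel geometry and the run structure. Voxels are stored
#' in a fixed, deterministic order — ascending slice (k), then row (j), then
#' column (i), i.e. the native column-major order of the 3-D array — so that
#' feature indices are stable across all operations.
#'
#' @param values numeric matrix, voxels x volumes.
#' @param voxel_coords integer matrix, voxels x 3, 0-based (i, j, k) indices.
#' @param voxel_dims voxel size in mm per axis.
#' @param tr_seconds repetition time in seconds.
#' @param run_ids run label per volume; runs must occupy contiguous volume
#'   ranges.
#' @param mask_shape dimensions of the underlying 3-D grid.
#' @return an object of class `mic_dataset`.
#' @export
mic_dataset <- function(values, voxel_coords, voxel_dims, tr_seconds,
                        run_ids, mask_shape) {
  values <- as.matrix(values)
  voxel_coords <- as.matrix(voxel_coords)
  if (nrow(values) != nrow(voxel_coords))
    stop("'values' and 'voxel_coords' disagree on the number of voxels")
  if (ncol(values) != length(run_ids))
    stop("'run_ids' must label every volume")
  if (anyNA(values)) stop("missing values in the time series")
  if (any(diff(match(run_ids, unique(run_ids))) < 0))
    stop("runs must occupy contiguous volume ranges")
  structure(list(values = values,
                 voxel_coords = voxel_coords,
                 voxel_dims = as.numeric(voxel_dims),
                 tr_seconds = tr_seconds,
                 run_ids = run_ids,
                 mask_shape = as.integer(mask_shape)),
            class = "mic_dataset")
}

#' @export
print.mic_dataset <- function(x, ...) {
  cat(sprintf("BOLD dataset: %d voxels x %d volumes, %d run(s), TR %g s, grid %s\n",
              nrow(x$values), ncol(x$values), length(unique(x$run_ids)),
              x$tr_seconds, paste(x$mask_shape, collapse = "x")))
  invisible(x)
}

#' @export
dim.mic_dataset <- function(x) dim(x$values)

#' Restrict a dataset to a subset of volumes or voxels
#'
#' @param ds a `mic_dataset`.
#' @param volumes,voxels index vectors (either may be omitted).
#' @return the restricted `mic_dataset`.
#' @export
subset_dataset <- function(ds, volumes = NULL, voxels = NULL) {
  if (is.null(volumes)) volumes <- seq_len(ncol(ds$values))
  if (is.null(voxels)) voxels <- seq_len(nrow(ds$values))
  mic_dataset(ds$values[voxels, volumes, drop = FALSE],
              ds$voxel_coords[voxels, , drop = FALSE],
              ds$voxel_dims, ds$tr_seconds,
              ds$run_ids[volumes], ds$mask_shape)
}

# Row indices of the dataset's voxels in the full 3-D grid (column-major).
voxel_linear_index <- function(coords, shape) {
  1L + coords[, 1L] + shape[1L] * (coords[, 2L] + shape[2L] * coords[, 3L])
}

# Inverse: 0-based (i, j, k) for column-major linear indices.
linear_to_coords <- function(idx, shape) {
  idx0 <- idx - 1L
  i <- idx0 %% shape[1L]
  j <- (idx0 %/% shape[1L]) %% shape[2L]
  k <- idx0 %/% (shape[1L] * shape[2L])
  cbind(i = i, j = j, k = k)
}

#' Read a masked 4-D BOLD volume
#'
#' Loads a NIfTI-1 4-D time series, applies a binary mask and returns the
#' in-mask voxels in the package's deterministic ordering.
#'
#' @param path path to the 4-D BOLD NIfTI file.
#' @param mask_path path to a binary 3-D mask NIfTI of the same grid.
#' @param run_ids optional run label per volume; defaults to a single run.
#' @param tr_seconds optional TR override; defaults to the NIfTI time pixdim.
#' @return a [mic_dataset()].
#' @export
read_bold <- function(path, mask_path, run_ids = NULL, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  mask <- RNifti::readNifti(mask_path)
  pad3 <- function(d) as.integer(c(d, 1L, 1L)[1:3])  # NIfTI may drop
  dims <- dim(img)                                   # singleton axes
  dims <- if (length(dims) >= 4L) dims else c(pad3(dims), 1L)
  if (!identical(pad3(dim(mask)), dims[1:3]))
    stop("BOLD and mask grids do not match")
  mvals <- as.vector(mask)
  if (!all(mvals %in% c(0, 1))) stop("mask is not binary")
  keep <- which(mvals == 1)
  if (length(keep) == 0L) stop("mask selects no voxels")
  n_vol <- dims[4L]
  values <- matrix(as.vector(img), prod(dims[1:3]), n_vol)[keep, , drop = FALSE]
  pd <- attr(img, "pixdim")
  if (is.null(tr_seconds)) tr_seconds <- if (length(pd) >= 4L) pd[4L] else 1
  if (is.null(run_ids)) run_ids <- rep(1L, n_vol)
  mic_dataset(values, linear_to_coords(keep, dims[1:3]),
              if (!is.null(pd)) pd[1:3] else c(1, 1, 1),
              tr_seconds, run_ids, dims[1:3])
}

#' Write a dataset as a 4-D NIfTI volume
#'
#' Voxels outside the dataset's mask are written as zero. The affine is the
#' diagonal of the voxel dimensions.
#'
#' @param ds a `mic_dataset`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold <- function(ds, path) {
  shape <- ds$mask_shape
  n_vol <- ncol(ds$values)
  arr <- array(0, c(shape, n_vol))
  lin <- voxel_linear_index(ds$voxel_coords, shape)
  flat <- matrix(arr, prod(shape), n_vol)
  flat[lin, ] <- ds$values
  arr <- array(flat, c(shape, n_vol))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(ds$voxel_dims, ds$tr_seconds)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a binary voxel mask as NIfTI
#'
#' @param path output path.
#' @param voxels integer matrix of 0-based (i, j, k) coordinates, or a
#'   logical/0-1 3-D array.
#' @param shape grid dimensions (ignored when `voxels` is an array).
#' @param voxel_dims voxel size in mm.
#' @return the path, invisibly.
#' @export
write_mask <- function(path, voxels, shape = NULL, voxel_dims = c(1, 1, 1)) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) {
    arr <- array(as.numeric(voxels != 0), dim(voxels))
  } else {
    voxels <- as.matrix(voxels)
    arr <- array(0, shape)
    arr[voxel_linear_index(voxels, shape)] <- 1
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_dims
  RNifti::writeNifti(nii, path)
  invisible(path)
}
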