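#' Place irregular connected informative regions in a voxel grid
#'
#' Grows each region from a random seed voxel by repeatedly annexing a
#' uniformly chosen face-neighbor of the current region, producing irregular
#' but connected ("realistically shaped") regions of exact size. Regions are
#' pairwise disjoint; placement is retried from scratch a bounded number of
#' times if a region gets boxed in.
#'
#' @param grid_shape integer vector of 3 voxel counts per axis.
#' @param region_size_voxels voxels per region.
#' @param n_regions number of regions.
#' @param seed integer seed for the placement stream.
#' @param max_retries attempts before giving up.
#' @return list with `regions` (a list of 0-based (i, j, k) coordinate
#'   matrices) and `mask` (logical 3-D array, TRUE inside any region).
#' @export
place_informative_regions <- function(grid_shape, region_size_voxels,
                                      n_regions = 2L, seed = 1L,
                                      max_retries = 200L) {
  grid_shape <- as.integer(grid_shape)
  n_total <- prod(grid_shape)
  if (region_size_voxels * n_regions > n_total)
    stop("requested regions do not fit in the grid")
  rng <- substream_rng(seed, "placement")
  for (attempt in seq_len(max_retries)) {
    taken <- logical(n_total)
    regions <- vector("list", n_regions)
    ok <- TRUE
    for (r in seq_len(n_regions)) {
      free <- which(!taken)
      start <- free[rng$sample_int(length(free), 1L)]
      members <- start
      taken[start] <- TRUE
      while (length(members) < region_size_voxels) {
        frontier <- setdiff(unique(unlist(
          lapply(members, face_neighbors, shape = grid_shape))),
          which(taken))
        if (length(frontier) == 0L) { ok <- FALSE; break }
        nxt <- frontier[rng$sample_int(length(frontier), 1L)]
        members <- c(members, nxt)
        taken[nxt] <- TRUE
      }
      if (!ok) break
      regions[[r]] <- linear_to_coords(sort(members), grid_shape)
    }
    if (ok) {
      mask <- array(FALSE, grid_shape)
      mask[which(taken)] <- TRUE
      return(list(regions = regions, mask = mask))
    }
  }
  stop("placement-failure: could not place disjoint connected regions")
}

# Face (6-connectivity) neighbors of a column-major linear index.
face_neighbors <- function(idx, shape) {
  co <- linear_to_coords(idx, shape)
  i <- co[1L]; j <- co[2L]; k <- co[3L]
  nb <- rbind(c(i - 1L, j, k), c(i + 1L, j, k),
              c(i, j - 1L, k), c(i, j + 1L, k),
              c(i, j, k - 1L), c(i, j, k + 1L))
  keep <- nb[, 1L] >= 0L & nb[, 1L] < shape[1L] &
    nb[, 2L] >= 0L & nb[, 2L] < shape[2L] &
    nb[, 3L] >= 0L & nb[, 3L] < shape[3L]
  nb <- nb[keep, , drop = FALSE]
  voxel_linear_index(nb, shape)
}

# Separable Gaussian smoothing of a flattened 4-D field.
# values: (prod(shape)) x n_vol matrix in column-major voxel order.
# Per-axis sigma (voxels) = (fwhm_mm / 2.3548) / voxel_dim; each 1-D kernel
# row is renormalized to unit sum so constants are preserved at the edges.
smooth_field <- function(values, shape, voxel_dims, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  n_vol <- ncol(values)
  arr <- array(values, c(shape, n_vol))
  for (ax in 1:3) {
    sig_vox <- sigma_mm / voxel_dims[ax]
    if (sig_vox < 1e-8) next
    n <- shape[ax]
    K <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sig_vox)
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    a <- array(K %*% matrix(a, n), dim(a))
    arr <- aperm(a, order(perm))
  }
  matrix(arr, prod(shape), n_vol)
}

#' Simulate a block-design BOLD dataset with known informative regions
#'
#' Implements the calibrated simulation: condition-specific Gaussian spatial
#' amplitude patterns are laid down in randomly placed connected informative
#' regions, modulated in time by the HRF-convolved block regressors, and
#' added to spatially smoothed Gaussian white noise. The signal is rescaled
#' by one global factor so that the measured contrast-to-noise ratio — the
#' spatial mean over informative voxels of the temporal maximum absolute
#' signal, divided by the pooled temporal standard deviation of the
#' post-smoothing noise — equals `config$cnr` exactly.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [mic_dataset()] over the full grid),
#'   `design` (the [build_block_design()] output) and `truth`, a
#'   `mic_groundtruth` holding the informative mask, per-condition spatial
#'   patterns, the scaled noise-free signal, the noise SD and the scale
#'   factor.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  shape <- config$grid_shape
  n_vox <- prod(shape)
  design <- build_block_design(config)
  vols_per_run <- attr(design, "volumes_per_run")
  n_vol <- nrow(design)

  # HRF-convolved regressors, convolved within each run independently
  hrf <- canonical_hrf(config$tr_seconds, 32)
  regs <- do.call(rbind, lapply(design_boxcars(design), function(bx) {
    apply(bx, 2, function(b)
      stats::convolve(b, rev(hrf), type = "open")[seq_along(b)])
  }))  # n_vol x n_conditions

  placement <- place_informative_regions(shape, config$region_size_voxels,
                                         config$n_regions, config$seed)
  inf_idx <- sort(unlist(lapply(placement$regions, function(co)
    voxel_linear_index(co, shape))))
  n_inf <- length(inf_idx)
  if (config$cnr > 0 && n_inf == 0L)
    stop("a positive CNR requires non-empty informative regions")

  pat_rng <- substream_rng(config$seed, "pattern")
  patterns <- matrix(pat_rng$rnorm(config$n_conditions * n_inf),
                     config$n_conditions, n_inf)

  # unit-scale signal: amplitude pattern x convolved regressor, per condition
  signal_unit <- tcrossprod(t(patterns), regs)  # n_inf x n_vol

  noise_rng <- substream_rng(config$seed, "noise")
  noise <- matrix(noise_rng$rnorm(n_vox * n_vol), n_vox, n_vol)
  noise <- smooth_field(noise, shape, config$voxel_dims, config$noise_fwhm_mm)
  noise_sigma <- sqrt(mean(row_variances(noise)))

  mean_max <- mean(apply(abs(signal_unit), 1L, max))
  scale <- if (config$cnr == 0 || mean_max == 0) 0 else
    config$cnr * noise_sigma / mean_max
  signal <- scale * signal_unit

  values <- noise
  values[inf_idx, ] <- values[inf_idx, ] + signal

  ds <- mic_dataset(values, linear_to_coords(seq_len(n_vox), shape),
                    config$voxel_dims, config$tr_seconds,
                    design$run, shape)
  inf_mask <- logical(n_vox)
  inf_mask[inf_idx] <- TRUE
  truth <- structure(list(informative_mask = inf_mask,
                          informative_index = inf_idx,
                          regions = placement$regions,
                          condition_patterns = patterns,
                          signal = signal,
                          noise_sigma = noise_sigma,
                          scale = scale),
                     class = "mic_groundtruth")
  list(dataset = ds, design = design, truth = truth)
}

#' Recompute the contrast-to-noise ratio from ground truth
#'
#' Applies the CNR definition to a simulation's ground truth: the spatial
#' mean over informative voxels of the temporal maximum absolute (scaled)
#' signal, divided by the temporal standard deviation of the post-smoothing
#' noise.
#'
#' @param truth a `mic_groundtruth` from [simulate_dataset()].
#' @return the measured CNR.
#' @export
measure_cnr <- function(truth) {
  if (nrow(truth$signal) == 0L) return(0)
  mean(apply(abs(truth$signal), 1L, max)) / truth$noise_sigma
}

row_variances <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1L)
}
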