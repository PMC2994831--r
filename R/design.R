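#' Simulation configuration
#'
#' Bundles and validates the parameters of the block-design BOLD simulator.
#' The defaults reproduce the reference simulation: a 32 x 32 x 5 grid of
#' 3 x 3 x 4 mm voxels, TR 2 s, eight runs each containing three 32-s blocks
#' per condition separated by 16-s fixation blocks, two conditions, noise
#' smoothed at 4 mm FWHM.
#'
#' @param grid_shape integer vector of 3 voxel counts per axis.
#' @param voxel_dims voxel size in mm per axis.
#' @param tr_seconds repetition time in seconds.
#' @param n_runs number of runs.
#' @param blocks_per_condition_per_run stimulus blocks per condition per run.
#' @param block_seconds stimulus block duration (s).
#' @param fixation_seconds fixation block duration (s).
#' @param n_conditions number of conditions (the simulator supports 2).
#' @param region_size_voxels voxels per informative region.
#' @param cnr target contrast-to-noise ratio (>= 0).
#' @param noise_fwhm_mm spatial FWHM of the Gaussian noise smoothing (mm).
#' @param n_regions number of informative regions.
#' @param seed master seed; all random components derive named substreams
#'   from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(32L, 32L, 5L),
                       voxel_dims = c(3, 3, 4),
                       tr_seconds = 2,
                       n_runs = 8L,
                       blocks_per_condition_per_run = 3L,
                       block_seconds = 32,
                       fixation_seconds = 16,
                       n_conditions = 2L,
                       region_size_voxels = 60L,
                       cnr = 0.2,
                       noise_fwhm_mm = 4,
                       n_regions = 2L,
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_dims = as.numeric(voxel_dims),
              tr_seconds = tr_seconds,
              n_runs = as.integer(n_runs),
              blocks_per_condition_per_run = as.integer(blocks_per_condition_per_run),
              block_seconds = block_seconds,
              fixation_seconds = fixation_seconds,
              n_conditions = as.integer(n_conditions),
              region_size_voxels = as.integer(region_size_voxels),
              cnr = cnr,
              noise_fwhm_mm = noise_fwhm_mm,
              n_regions = as.integer(n_regions),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L),
            length(cfg$voxel_dims) == 3L, all(cfg$voxel_dims > 0),
            cfg$tr_seconds > 0, cfg$n_runs >= 1L,
            cfg$blocks_per_condition_per_run >= 1L,
            cfg$n_conditions == 2L, cfg$n_regions >= 1L)
  for (d in c(cfg$block_seconds, cfg$fixation_seconds)) {
    if (d <= 0 || abs(d / cfg$tr_seconds - round(d / cfg$tr_seconds)) > 1e-9)
      stop("block and fixation durations must be positive multiples of the TR")
  }
  if (cfg$region_size_voxels < 1L ||
      cfg$region_size_voxels * cfg$n_regions > prod(cfg$grid_shape))
    stop("informative regions do not fit in the grid")
  if (cfg$cnr < 0) stop("'cnr' must be non-negative")
  invisible(cfg)
}

#' Build the block design of a simulated experiment
#'
#' Lays out each run as an initial fixation block followed by alternating
#' stimulus and fixation blocks. The order of the stimulus blocks within a
#' run is a seeded random permutation of the condition slots (three blocks
#' per condition by default), so that condition order never confounds the
#' cross-validation folds.
#'
#' @param config a [sim_config()].
#' @return an object of class `mic_design`: a data frame with one row per
#'   volume and columns `run`, `volume` (0-based within run) and `condition`
#'   (0 for fixation, 1..n for the conditions), plus attributes
#'   `boxcars` (a volumes x conditions binary matrix per run, concatenated)
#'   and `volumes_per_run`.
#' @export
build_block_design <- function(config) {
  validate_sim_config(config)
  tr <- config$tr_seconds
  block_vols <- as.integer(round(config$block_seconds / tr))
  fix_vols <- as.integer(round(config$fixation_seconds / tr))
  n_blocks <- config$n_conditions * config$blocks_per_condition_per_run
  vols_per_run <- fix_vols + n_blocks * (block_vols + fix_vols)

  rows <- vector("list", config$n_runs)
  rng <- substream_rng(config$seed, "block_order")
  for (r in seq_len(config$n_runs)) {
    order_r <- rng$permute(rep(seq_len(config$n_conditions),
                               each = config$blocks_per_condition_per_run))
    cond <- rep(0L, vols_per_run)
    pos <- fix_vols
    for (b in seq_len(n_blocks)) {
      cond[pos + seq_len(block_vols)] <- order_r[b]
      pos <- pos + block_vols + fix_vols
    }
    rows[[r]] <- data.frame(run = r, volume = seq_len(vols_per_run) - 1L,
                            condition = cond)
  }
  design <- do.call(rbind, rows)
  class(design) <- c("mic_design", "data.frame")
  attr(design, "volumes_per_run") <- vols_per_run
  design
}

#' @export
print.mic_design <- function(x, ...) {
  cat(sprintf("Block design: %d runs x %d volumes, %d conditions\n",
              length(unique(x$run)), attr(x, "volumes_per_run"),
              max(x$condition)))
  invisible(x)
}

#' Per-condition boxcar regressors of a design
#'
#' @param design a `mic_design`.
#' @return list with one binary matrix (volumes x conditions) per run.
#' @export
design_boxcars <- function(design) {
  n_cond <- max(design$condition)
  lapply(split(design$condition, design$run), function(cond) {
    vapply(seq_len(n_cond), function(k) as.numeric(cond == k),
           numeric(length(cond)))
  })
}
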