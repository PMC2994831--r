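# Small in-code fixtures shared across test files.

# Dataset covering a full grid, values supplied as voxels x volumes.
grid_dataset <- function(values, shape, tr = 2, run_ids = NULL,
                         voxel_dims = c(1, 1, 1)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == prod(shape))
  if (is.null(run_ids)) run_ids <- rep(1L, ncol(values))
  coords <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1L,
                                  j = seq_len(shape[2]) - 1L,
                                  k = seq_len(shape[3]) - 1L))
  mic_dataset(values, coords, voxel_dims, tr, run_ids, shape)
}

# Reduced-scale simulation config for fast tests: smaller grid, fewer runs.
tiny_sim_config <- function(cnr = 0.2, n_runs = 4L,
                            region_size_voxels = 15L, ...) {
  sim_config(grid_shape = c(12L, 12L, 4L), n_runs = n_runs,
             region_size_voxels = region_size_voxels, cnr = cnr, ...)
}

# Balanced two-class pattern set with a mean shift on the first n_inf
# features.
toy_patterns <- function(n_per_class = 10, n_feat = 6, n_inf = 2,
                         effect = 2, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_feat), n, n_feat)
  labels <- rep(c(1L, 2L), each = n_per_class)
  x[labels == 1L, seq_len(n_inf)] <- x[labels == 1L, seq_len(n_inf)] + effect
  mic_patterns(x, labels, runs = rep(seq_len(n_per_class), 2))
}
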