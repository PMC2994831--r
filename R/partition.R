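#' Homogeneous-cluster partition
#'
#' Disjoint, spatially connected voxel clusters plus the set of voxels left
#' unclustered, as produced by [region_grow()] or [cubic_partition()].
#' Finished clusters from region growing always have sizes in
#' `[Ts, 2 (Ts - 1)]`: they are formed by merging two sub-threshold pieces
#' (each at most `Ts - 1` voxels) and retired as soon as they reach `Ts`.
#'
#' @param clusters list of integer vectors of voxel row indices.
#' @param excluded integer vector of unclustered voxel row indices.
#' @param Ts the size threshold used (NA for cubic partitions).
#' @param connectivity `"face"` or `"edge-corner"`.
#' @param n_voxels total voxels in the originating dataset.
#' @return an object of class `mic_partition`.
#' @export
mic_partition <- function(clusters, excluded, Ts, connectivity, n_voxels) {
  structure(list(clusters = clusters, excluded = excluded, Ts = Ts,
                 connectivity = connectivity, n_voxels = n_voxels),
            class = "mic_partition")
}

#' @export
print.mic_partition <- function(x, ...) {
  cat(sprintf("Partition: %d clusters (sizes %s), %d excluded of %d voxels\n",
              length(x$clusters),
              if (length(x$clusters)) paste(range(lengths(x$clusters)),
                                            collapse = "-") else "-",
              length(x$excluded), x$n_voxels))
  invisible(x)
}

# Center rows and scale them to unit norm so that a dot product of two rows
# is their Pearson correlation. Rows with zero temporal variance become zero
# vectors, making every correlation involving them 0.
standardize_series <- function(values) {
  z <- values - rowMeans(values)
  nrm <- sqrt(rowSums(z * z))
  nrm[nrm == 0] <- Inf
  z / nrm
}

#' Mean pairwise time-series correlation between two clusters
#'
#' The similarity driving the competitive region growing: the average of the
#' Pearson correlations between the raw time series of every cross pair of
#' voxels, one from each cluster. Correlations involving a constant
#' (zero-variance) voxel are defined as 0.
#'
#' @param clusterA,clusterB integer vectors of voxel row indices.
#' @param ds a [mic_dataset()].
#' @return the mean cross-pair correlation; symmetric in its cluster
#'   arguments.
#' @export
cluster_similarity <- function(clusterA, clusterB, ds) {
  if (length(clusterA) == 0L || length(clusterB) == 0L)
    stop("clusters must be non-empty")
  if (ncol(ds$values) < 3L) stop("time series must have length >= 3")
  z <- standardize_series(ds$values[union(clusterA, clusterB), , drop = FALSE])
  rownames(z) <- as.character(union(clusterA, clusterB))
  sA <- colSums(z[as.character(clusterA), , drop = FALSE])
  sB <- colSums(z[as.character(clusterB), , drop = FALSE])
  sum(sA * sB) / (length(clusterA) * length(clusterB))
}

# Pairs of adjacent in-mask voxels (rows of ds) under the given connectivity.
voxel_adjacency_pairs <- function(ds, connectivity = "face") {
  shape <- ds$mask_shape
  lin <- voxel_linear_index(ds$voxel_coords, shape)
  pos <- integer(prod(shape))
  pos[lin] <- seq_along(lin)
  offsets <- if (connectivity == "face") {
    rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    o <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
    o[o %*% c(1, 3, 9) > 0, , drop = FALSE]  # one of each +/- pair
  }
  from <- integer(); to <- integer()
  for (r in seq_len(nrow(offsets))) {
    co2 <- sweep(ds$voxel_coords, 2L, offsets[r, ], "+")
    ok <- co2[, 1L] >= 0L & co2[, 1L] < shape[1L] &
      co2[, 2L] >= 0L & co2[, 2L] < shape[2L] &
      co2[, 3L] >= 0L & co2[, 3L] < shape[3L]
    nb <- pos[voxel_linear_index(co2[ok, , drop = FALSE], shape)]
    f <- which(ok)[nb > 0L]
    from <- c(from, f); to <- c(to, nb[nb > 0L])
  }
  cbind(from, to)
}

#' Partition a dataset by competitive region growing
#'
#' Iterative agglomeration on raw time-series correlation. Every voxel
#' starts as a candidate cluster. In each iteration, each candidate names
#' the adjacent candidate with which its mean pairwise correlation
#' ([cluster_similarity()]) is highest; every pair of mutual nearest
#' neighbors is merged simultaneously. A merged cluster whose size has
#' reached the threshold `Ts` is retired from the candidate set as a
#' finished homogeneous cluster. The process stops when no candidates
#' remain or no mutual pair exists; surviving candidates are marked
#' excluded. All ties are broken toward the lower cluster id (ids assigned
#' in voxel lexicographic order), making the partition deterministic.
#'
#' @param ds a [mic_dataset()].
#' @param Ts minimum cluster size threshold (>= 2).
#' @param connectivity `"face"` (6-neighborhood, default) or `"edge-corner"`
#'   (26-neighborhood).
#' @return a [mic_partition()].
#' @export
region_grow <- function(ds, Ts, connectivity = c("face", "edge-corner")) {
  connectivity <- match.arg(connectivity)
  if (Ts < 2L) stop("'Ts' must be at least 2")
  n_vox <- nrow(ds$values)
  if (n_vox == 0L) stop("empty mask")
  Z <- standardize_series(ds$values)
  vp <- voxel_adjacency_pairs(ds, connectivity)

  cid <- seq_len(n_vox)              # candidate cluster id per voxel
  S <- Z                             # per-cluster summed standardized series
  sizes <- rep(1L, n_vox)
  active <- rep(TRUE, n_vox)         # candidate (not finished) clusters
  members <- as.list(seq_len(n_vox))
  finished <- list()

  repeat {
    if (!any(active)) break
    a1 <- cid[vp[, 1L]]; a2 <- cid[vp[, 2L]]
    keep <- a1 != a2 & active[a1] & active[a2]
    if (!any(keep)) break
    i <- pmin(a1[keep], a2[keep]); j <- pmax(a1[keep], a2[keep])
    key <- as.numeric(i) * (n_vox + 1) + j
    uq <- !duplicated(key)
    i <- i[uq]; j <- j[uq]
    sims <- rowSums(S[i, , drop = FALSE] * S[j, , drop = FALSE]) /
      (as.numeric(sizes[i]) * sizes[j])

    from <- c(i, j); to <- c(j, i); sim2 <- c(sims, sims)
    ord <- order(from, -sim2, to)
    first <- !duplicated(from[ord])
    best <- integer(n_vox)
    best[from[ord][first]] <- to[ord][first]

    cand <- which(best > 0L)
    mutual <- cand[best[best[cand]] == cand & cand < best[cand]]
    if (length(mutual) == 0L) break

    for (a in mutual) {
      b <- best[a]
      S[a, ] <- S[a, ] + S[b, ]
      sizes[a] <- sizes[a] + sizes[b]
      members[[a]] <- c(members[[a]], members[[b]])
      cid[members[[b]]] <- a
      members[[b]] <- integer()
      active[b] <- FALSE
      if (sizes[a] >= Ts) {
        finished[[length(finished) + 1L]] <- sort(members[[a]])
        active[a] <- FALSE
      }
    }
  }
  excluded <- sort(unlist(members[active]))
  if (length(finished))
    finished <- finished[order(vapply(finished, min, integer(1L)))]
  mic_partition(finished, as.integer(excluded), Ts, connectivity, n_vox)
}

#' Partition a dataset into cubic clusters
#'
#' Baseline partition ignoring functional homogeneity: the grid is tiled
#' with non-overlapping rectangular blocks and each cluster is the set of
#' in-mask voxels falling in one block. Blocks covered at half the nominal
#' volume or less are marked excluded.
#'
#' @param ds a [mic_dataset()].
#' @param block_dims integer vector of 3 block edge lengths in voxels
#'   (e.g. `c(3, 3, 2)` for 18-voxel clusters).
#' @return a [mic_partition()] with `Ts = NA`.
#' @export
cubic_partition <- function(ds, block_dims) {
  block_dims <- as.integer(block_dims)
  if (any(block_dims < 1L)) stop("'block_dims' must be positive")
  bid <- ds$voxel_coords %/% matrix(block_dims, nrow(ds$voxel_coords), 3L,
                                    byrow = TRUE)
  nb <- ceiling(ds$mask_shape / block_dims)
  key <- bid[, 1L] + nb[1L] * (bid[, 2L] + nb[2L] * bid[, 3L])
  groups <- split(seq_len(nrow(ds$voxel_coords)), key)
  nominal <- prod(block_dims)
  keep <- lengths(groups) * 2L > nominal
  clusters <- unname(lapply(groups[keep], as.integer))
  if (length(clusters))
    clusters <- clusters[order(vapply(clusters, min, integer(1L)))]
  mic_partition(clusters, as.integer(sort(unlist(groups[!keep]))),
                NA_integer_, "face", nrow(ds$values))
}

#' Mean within-cluster pairwise correlation
#'
#' Average Pearson correlation over all within-cluster voxel pairs, per
#' cluster — the homogeneity summary of a partition.
#'
#' @param ds a [mic_dataset()].
#' @param partition a [mic_partition()].
#' @return numeric vector, one mean correlation per cluster (NA for
#'   singletons).
#' @export
cluster_homogeneity <- function(ds, partition) {
  Z <- standardize_series(ds$values)
  vapply(partition$clusters, function(cl) {
    n <- length(cl)
    if (n < 2L) return(NA_real_)
    s <- colSums(Z[cl, , drop = FALSE])
    (sum(s * s) - sum(rowSums(Z[cl, , drop = FALSE]^2))) / (n * (n - 1L))
  }, numeric(1L))
}
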