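#' Assign runs to cross-validation folds
#'
#' Runs are shuffled under the seed and dealt round-robin, so each run is
#' tested exactly once and fold sizes differ by at most one run.
#'
#' @param run_ids run label per volume or per sample (only the distinct
#'   values matter).
#' @param k number of folds.
#' @param seed shuffle seed; repetitions of the cross-validation differ
#'   only by this seed.
#' @return an object of class `mic_folds`: `k` plus a named vector mapping
#'   each run to its test fold.
#' @export
make_folds <- function(run_ids, k = 4L, seed = 1L) {
  runs <- unique(run_ids)
  if (k > length(runs)) stop("more folds than runs")
  shuffled <- substream_rng(seed, "folds")$permute(runs)
  assignment <- rep(seq_len(k), length.out = length(runs))
  names(assignment) <- as.character(shuffled)
  structure(list(k = as.integer(k), assignment = assignment),
            class = "mic_folds")
}

#' Fraction of correctly predicted labels
#'
#' @param predicted,truth equal-length label vectors.
#' @return proportion correct in `[0, 1]`.
#' @export
predictive_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    stop("need equal-length, non-empty label vectors")
  mean(predicted == truth)
}

#' ROC curve and AUC of a weight map against ground truth
#'
#' Sweeps a threshold over the distinct weight values; at each threshold
#' sensitivity is the fraction of truly informative voxels with weight at or
#' above it, and 1 - specificity the corresponding fraction of uninformative
#' voxels. The area is computed by the trapezoidal rule over the full curve,
#' anchored at (0, 0) and (1, 1), which makes it identical to the
#' tie-corrected Mann-Whitney U statistic normalized by the number of
#' informative x uninformative voxel pairs.
#'
#' @param weights numeric per-voxel weight vector (e.g. `$w` of a
#'   [voxel_weight_map()]).
#' @param truth_mask logical per-voxel indicator of the informative voxels.
#' @return list with `fpr`, `tpr` (curve points) and `auc`.
#' @export
roc_auc <- function(weights, truth_mask) {
  truth_mask <- as.logical(truth_mask)
  if (length(weights) != length(truth_mask))
    stop("weights and truth differ in length")
  if (all(truth_mask) || !any(truth_mask))
    stop("ground truth must contain both classes")
  thr <- sort(unique(weights), decreasing = TRUE)
  n_pos <- sum(truth_mask); n_neg <- sum(!truth_mask)
  pos_at <- vapply(thr, function(t) sum(weights[truth_mask] >= t), numeric(1L))
  neg_at <- vapply(thr, function(t) sum(weights[!truth_mask] >= t), numeric(1L))
  tpr <- c(0, pos_at / n_pos)
  fpr <- c(0, neg_at / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Robustness of mapping: mean pairwise set similarity
#'
#' The stability of feature selection across folds, measured as the mean
#' over all unordered pairs of selected sets of the intersection-over-union
#' similarity: 1 for identical sets, 0 for disjoint ones. A pair of empty
#' sets counts as similarity 1.
#'
#' @param selected_sets list of at least two voxel-index sets.
#' @return mean pairwise similarity in `[0, 1]`.
#' @export
robustness <- function(selected_sets) {
  n <- length(selected_sets)
  if (n < 2L) stop("need at least two sets")
  sims <- numeric(0L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    sims <- c(sims, overlap_rate(selected_sets[[i]], selected_sets[[j]]))
  mean(sims)
}

#' Overlap rate between two voxel sets
#'
#' Intersection over union of two sets; the same similarity used for the
#' robustness of mapping, applied to a single pair (e.g. informative sets
#' mapped in two different contrasts). Two empty sets have overlap 1.
#'
#' @param setA,setB voxel-index vectors.
#' @return similarity in `[0, 1]`.
#' @export
overlap_rate <- function(setA, setB) {
  u <- length(union(setA, setB))
  if (u == 0L) return(1)
  length(intersect(setA, setB)) / u
}

#' Cross-validated mapping and classification
#'
#' Runs one repetition of the cross-validated informative-mapping pipeline
#' for one or more methods on the same data and fold plan. Per fold, the
#' mapping (partition, summarization, SVM weight ranking) uses the training
#' runs only; at each feature level an SVM is retrained on the selected
#' features and scored on the held-out runs. For the cluster methods the
#' homogeneous partition is recomputed per fold from the training runs' raw
#' time series. Methods:
#' \describe{
#'   \item{MIV}{voxel features from the whole brain.}
#'   \item{MIVs}{MIV on data spatially smoothed at `smooth_fwhm_mm`.}
#'   \item{uMIC}{cluster features: spatial means over homogeneous clusters.}
#'   \item{mMIC}{cluster features: GNB discriminants over homogeneous
#'     clusters.}
#'   \item{mMICc}{mMIC on a cubic (non-homogeneous) partition.}
#' }
#'
#' @param ds a [mic_dataset()].
#' @param design the aligned `mic_design`.
#' @param methods character vector of methods to run.
#' @param folds a [make_folds()] plan over the design's runs.
#' @param Ts region-growing size threshold (cluster methods).
#' @param block_dims cubic block dimensions (mMICc).
#' @param C SVM regularization constant.
#' @param levels feature levels (voxel counts); levels exceeding the voxels
#'   available to a method are dropped with a warning.
#' @param shift_volumes hemodynamic shift for block averaging.
#' @param smooth_fwhm_mm smoothing FWHM for MIVs.
#' @param partition_scope `"dataset"` (default) grows the homogeneous
#'   partition once from the full raw time series — parcellation is
#'   unsupervised and uses no condition labels, so it can precede the
#'   cross-validation; `"fold"` recomputes it per fold from the training
#'   runs only, the strictest train/test separation.
#' @param truth optional `mic_groundtruth` for ROC/AUC.
#' @return named list (one per method) of `mic_mapping_result` objects with
#'   per-fold accuracies and selected sets, per-level mean accuracy and
#'   robustness, `max_accuracy`, `mean_robustness` and (with truth)
#'   `mean_auc`.
#' @export
mic_cv <- function(ds, design, methods = c("mMIC", "MIV"),
                   folds = make_folds(design$run),
                   Ts = 15L, block_dims = c(3L, 3L, 2L), C = 1,
                   levels = feature_levels(), shift_volumes = 3L,
                   smooth_fwhm_mm = 6,
                   partition_scope = c("dataset", "fold"), truth = NULL) {
  partition_scope <- match.arg(partition_scope)
  known <- c("MIV", "MIVs", "uMIC", "mMIC", "mMICc")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  n_vox <- nrow(ds$values)
  patterns <- extract_patterns(ds, design, shift_volumes)
  patterns_s <- if ("MIVs" %in% methods)
    extract_patterns(gaussian_smooth(ds, smooth_fwhm_mm), design,
                     shift_volumes)
  cubic <- if ("mMICc" %in% methods) cubic_partition(ds, block_dims)
  need_rg <- any(c("uMIC", "mMIC") %in% methods)
  part_shared <- if (need_rg && partition_scope == "dataset")
    region_grow(ds, Ts)

  res <- lapply(methods, function(m)
    list(fold_acc = NULL, fold_auc = numeric(0L), selected = list()))
  names(res) <- methods

  for (f in seq_len(folds$k)) {
    test_runs <- names(folds$assignment)[folds$assignment == f]
    train_vol <- which(!(as.character(design$run) %in% test_runs))
    tr_idx <- which(!(as.character(patterns$runs) %in% test_runs))
    te_idx <- which(as.character(patterns$runs) %in% test_runs)

    part_rg <- if (need_rg) {
      if (partition_scope == "dataset") part_shared
      else region_grow(subset_dataset(ds, volumes = train_vol), Ts)
    }

    for (m in methods) {
      p <- if (m == "MIVs") patterns_s else patterns
      tr <- subset_patterns(p, tr_idx)
      te <- subset_patterns(p, te_idx)
      part <- switch(m, uMIC = part_rg, mMIC = part_rg, mMICc = cubic, NULL)
      if (m == "uMIC") {
        tr <- summarize_umic(tr, part)
        te <- summarize_umic(te, part)
      } else if (m %in% c("mMIC", "mMICc")) {
        mm <- summarize_mmic(tr, te, part)
        tr <- mm$train; te <- mm$test
      }
      model <- train_linear_svm(tr$x, tr$labels, C)
      wmap <- voxel_weight_map(model, tr, n_vox, part)
      if (!is.null(truth))
        res[[m]]$fold_auc <- c(res[[m]]$fold_auc,
                               roc_auc(wmap$w, truth$informative_mask)$auc)

      avail <- if (wmap$kind == "voxel") length(wmap$feature_voxels)
      else sum(lengths(wmap$clusters))
      use_levels <- levels[levels <= avail]
      if (length(use_levels) < length(levels))
        warning(sprintf("%s: dropped %d feature level(s) above %d voxels",
                        m, length(levels) - length(use_levels), avail))
      acc <- sets <- vector("list", length(use_levels))
      for (li in seq_along(use_levels)) {
        sel <- select_voxels(wmap, use_levels[li])
        if (wmap$kind == "voxel") {
          cols <- match(sel, p$feature_map)
          xtr <- p$x[tr_idx, cols, drop = FALSE]
          xte <- p$x[te_idx, cols, drop = FALSE]
        } else {
          cols <- selected_clusters(wmap, sel)
          xtr <- tr$x[, cols, drop = FALSE]
          xte <- te$x[, cols, drop = FALSE]
        }
        lvl_model <- train_linear_svm(xtr, tr$labels, C)
        acc[[li]] <- predictive_accuracy(
          predict(lvl_model, xte), te$labels)
        sets[[li]] <- sel
      }
      res[[m]]$fold_acc <- rbind(res[[m]]$fold_acc, unlist(acc))
      res[[m]]$selected[[f]] <- sets
      res[[m]]$levels <- use_levels
    }
  }

  lapply(res, function(r) {
    level_acc <- colMeans(r$fold_acc)
    level_rob <- vapply(seq_along(r$levels), function(li)
      robustness(lapply(r$selected, `[[`, li)), numeric(1L))
    structure(list(levels = r$levels,
                   fold_acc = r$fold_acc,
                   level_accuracy = level_acc,
                   max_accuracy = max(level_acc),
                   level_robustness = level_rob,
                   mean_robustness = mean(level_rob),
                   fold_auc = r$fold_auc,
                   mean_auc = if (length(r$fold_auc)) mean(r$fold_auc),
                   selected = r$selected),
              class = "mic_mapping_result")
  })
}

#' @export
print.mic_mapping_result <- function(x, ...) {
  cat(sprintf("Mapping result: max accuracy %.3f, mean robustness %.3f%s\n",
              x$max_accuracy, x$mean_robustness,
              if (!is.null(x$mean_auc))
                sprintf(", mean AUC %.3f", x$mean_auc) else ""))
  invisible(x)
}

#' Run one mapping method through cross-validation
#'
#' Convenience wrapper around [mic_cv()] for a single method.
#'
#' @inheritParams mic_cv
#' @param method one of `"MIV"`, `"MIVs"`, `"uMIC"`, `"mMIC"`, `"mMICc"`.
#' @param ... passed to [mic_cv()].
#' @return a `mic_mapping_result`.
#' @export
run_pipeline <- function(method, ds, design, ...) {
  mic_cv(ds, design, methods = method, ...)[[1L]]
}
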