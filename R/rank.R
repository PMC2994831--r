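#' Train a linear support vector machine
#'
#' Soft-margin linear SVM minimizing `||w||^2 / 2 + C * sum(hinge)` via the
#' LIBSVM solver. The decision function is oriented so that positive values
#' favor the positive class: `+1` for numeric `+1/-1` labels, otherwise the
#' first of `sort(unique(y))` (condition 1 for `{1, 2}` labels).
#'
#' @param x numeric matrix, samples x features.
#' @param y two-class label per sample (any two distinct values).
#' @param C regularization constant (> 0).
#' @param tolerance solver stopping tolerance.
#' @return an object of class `mic_svm` with fields `w`, `b`, `C`,
#'   `positive_class`.
#' @export
train_linear_svm <- function(x, y, C = 1, tolerance = 1e-7) {
  x <- as.matrix(x)
  if (C <= 0) stop("'C' must be positive")
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("exactly two classes are required")
  # +1/-1 labels keep the conventional orientation (+1 positive); any other
  # label set takes its first sorted value as the positive class
  if (is.numeric(y) && identical(as.numeric(classes), c(-1, 1)))
    classes <- rev(classes)
  yf <- factor(y, levels = classes)
  fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  # Dual variables alpha are orientation-free (Q and y'alpha = 0 are
  # invariant under a global label flip), so rebuild w in our orientation:
  # yy = +1 for the positive class.
  yy <- ifelse(y == classes[1L], 1, -1)
  alpha <- numeric(nrow(x))
  alpha[fit$index] <- abs(as.numeric(fit$coefs))
  alpha <- polish_svm_alpha(alpha, x, yy, C)
  w <- as.numeric(crossprod(x, alpha * yy))
  b <- svm_intercept(w, x, yy, C, alpha)
  structure(list(w = w, b = b, C = C, positive_class = classes[1L],
                 classes = classes),
            class = "mic_svm")
}

# One exact KKT refinement of the LIBSVM dual solution: fix the active set
# implied by alpha, solve the stationarity system on the free block, and
# keep the result if it stays feasible. Removes the solver's termination
# slack from the reported solution.
polish_svm_alpha <- function(alpha, x, yy, C) {
  eps <- 1e-6 * C
  Fr <- which(alpha > eps & alpha < C - eps)
  up <- which(alpha >= C - eps)
  a <- numeric(length(alpha))
  a[up] <- C
  if (length(Fr) > 0L) {
    Q <- tcrossprod(x) * tcrossprod(yy)
    A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], yy[Fr]), c(yy[Fr], 0))
    rhs <- c(1 - Q[Fr, up, drop = FALSE] %*% rep(C, length(up)),
             -sum(yy[up]) * C)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return(alpha)
    a[Fr] <- sol[seq_along(Fr)]
    if (any(a[Fr] < 0 | a[Fr] > C)) return(alpha)
  } else if (abs(sum(yy * a)) > 1e-9) {
    return(alpha)
  }
  a
}

# Optimal intercept for a fixed w: from margin (free) support vectors when
# available, otherwise by exact minimization of the piecewise-linear primal
# over its breakpoints.
svm_intercept <- function(w, x, yy, C, alpha) {
  eps <- 1e-6 * C
  Fr <- which(alpha > eps & alpha < C - eps)
  fx <- as.numeric(x %*% w)
  if (length(Fr) > 0L) return(mean(yy[Fr] - fx[Fr]))
  obj <- function(b) 0.5 * sum(w^2) + C * sum(pmax(0, 1 - yy * (fx + b)))
  bp <- yy - fx
  vals <- vapply(bp, obj, numeric(1L))
  opt <- bp[vals <= min(vals) + 1e-12]
  mean(range(opt))
}

#' Decision values of a linear SVM
#'
#' @param model a [train_linear_svm()] model.
#' @param x samples x features matrix.
#' @return numeric vector `x %*% w + b`.
#' @export
decision_values <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$w)) stop("feature count mismatch")
  as.numeric(x %*% model$w + model$b)
}

#' @describeIn train_linear_svm Predict class labels; a decision value of
#'   exactly zero maps to the positive class.
#' @param object a `mic_svm` model.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @export
predict.mic_svm <- function(object, newdata, ...) {
  d <- decision_values(object, newdata)
  ifelse(d >= 0, object$classes[1L], object$classes[2L])
}

#' Rank features by absolute discriminative weight
#'
#' @param model a [train_linear_svm()] model.
#' @return integer vector of feature indices sorted by decreasing `|w|`,
#'   ties broken toward the lower index.
#' @export
rank_features <- function(model) {
  order(-abs(model$w), seq_along(model$w))
}

#' Geometric progression of feature levels
#'
#' Voxel counts at which mapping and classification are evaluated: a
#' geometric sequence from `min_voxels` to `max_voxels` with ratio
#' `(max/min)^(1/(n_levels - 1))`, each term rounded to the nearest integer.
#' The defaults give 100, 150, 225, ..., 3844.
#'
#' @param min_voxels smallest level.
#' @param max_voxels largest level.
#' @param n_levels number of levels.
#' @return strictly increasing integer vector of length `n_levels`.
#' @export
feature_levels <- function(min_voxels = 100L, max_voxels = 3844L,
                           n_levels = 10L) {
  if (min_voxels >= max_voxels || n_levels < 2L)
    stop("need min_voxels < max_voxels and at least 2 levels")
  r <- (max_voxels / min_voxels)^(1 / (n_levels - 1))
  lv <- as.integer(round(min_voxels * r^(0:(n_levels - 1L))))
  if (any(diff(lv) <= 0L)) stop("levels are not strictly increasing")
  lv
}

#' Per-voxel map of absolute discriminative weights
#'
#' Projects a trained SVM's weights back to voxel space. For voxel features
#' each voxel carries its own `|w|`; for cluster features every voxel of a
#' cluster carries the cluster's `|w|`. Voxels outside the feature set
#' (e.g. excluded by the partition) carry weight 0.
#'
#' @param model a [train_linear_svm()] model.
#' @param patterns the [mic_patterns()] the model was trained on.
#' @param n_voxels total voxels of the originating dataset.
#' @param partition the [mic_partition()] behind cluster features.
#' @return an object of class `mic_weight_map`.
#' @export
voxel_weight_map <- function(model, patterns, n_voxels, partition = NULL) {
  aw <- abs(model$w)
  w <- numeric(n_voxels)
  if (patterns$feature_kind == "voxel") {
    w[patterns$feature_map] <- aw
    structure(list(w = w, kind = "voxel",
                   feature_voxels = patterns$feature_map),
              class = "mic_weight_map")
  } else {
    if (is.null(partition)) stop("cluster features require the partition")
    if (length(partition$clusters) != length(aw))
      stop("partition and model disagree on the number of clusters")
    for (h in seq_along(partition$clusters)) w[partition$clusters[[h]]] <- aw[h]
    structure(list(w = w, kind = "cluster", clusters = partition$clusters,
                   cluster_w = aw),
              class = "mic_weight_map")
  }
}

#' Select the most informative voxels at a feature level
#'
#' For voxel maps, takes the `n_voxels` voxels of largest weight (ties
#' toward the lower voxel index). For cluster maps, admits whole clusters
#' in decreasing weight order (ties toward the lower cluster id) while they
#' fit, then fills the remainder from the next cluster in ascending voxel
#' order, so that cluster- and voxel-based mappings are comparable at
#' identical voxel counts.
#'
#' @param weight_map a [voxel_weight_map()].
#' @param n_voxels number of voxels to select.
#' @return sorted integer vector of selected voxel row indices.
#' @export
select_voxels <- function(weight_map, n_voxels) {
  if (weight_map$kind == "voxel") {
    fv <- weight_map$feature_voxels
    if (n_voxels > length(fv)) stop("n_voxels exceeds the available voxels")
    ord <- fv[order(-weight_map$w[fv], fv)]
    return(sort(ord[seq_len(n_voxels)]))
  }
  sizes <- lengths(weight_map$clusters)
  if (n_voxels > sum(sizes)) stop("n_voxels exceeds the available voxels")
  rank <- order(-weight_map$cluster_w, seq_along(weight_map$cluster_w))
  selected <- integer(0L)
  for (h in rank) {
    cl <- sort(weight_map$clusters[[h]])
    room <- n_voxels - length(selected)
    if (room <= 0L) break
    selected <- c(selected, cl[seq_len(min(room, length(cl)))])
  }
  sort(selected)
}

#' Clusters touched by a voxel selection
#'
#' @param weight_map a cluster-kind [voxel_weight_map()].
#' @param selected voxel set from [select_voxels()].
#' @return integer ids of clusters with at least one selected voxel.
#' @export
selected_clusters <- function(weight_map, selected) {
  which(vapply(weight_map$clusters,
               function(cl) any(cl %in% selected), logical(1L)))
}
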