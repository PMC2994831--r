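#' Univariate within-cluster summarization (uMIC)
#'
#' Collapses each cluster's multi-voxel pattern to its spatial mean,
#' producing one value per sample per cluster — the regions-of-interest
#' style summary, appropriate when within-cluster voxels are treated as
#' samples from one shared response distribution.
#'
#' @param patterns a voxel-feature [mic_patterns()].
#' @param partition a [mic_partition()] over the same voxels.
#' @return a cluster-feature [mic_patterns()] (samples x clusters).
#' @export
summarize_umic <- function(patterns, partition) {
  check_partition_features(patterns, partition)
  x <- vapply(partition$clusters, function(cl) {
    rowMeans(patterns$x[, match(cl, patterns$feature_map), drop = FALSE])
  }, numeric(nrow(patterns$x)))
  x <- matrix(x, nrow = nrow(patterns$x))
  mic_patterns(x, patterns$labels, patterns$runs, "cluster",
               seq_along(partition$clusters))
}

check_partition_features <- function(patterns, partition) {
  if (length(partition$clusters) == 0L) stop("partition has no clusters")
  if (any(lengths(partition$clusters) == 0L)) stop("empty cluster")
  if (anyNA(match(unlist(partition$clusters), patterns$feature_map)))
    stop("partition refers to voxels absent from the pattern set")
  invisible(TRUE)
}

#' Fit a per-cluster Gaussian naive Bayes model
#'
#' Estimates, for every voxel of one cluster, Gaussian class-conditional
#' densities from training samples: per-class means, and
#' (maximum-likelihood, i.e. biased) variances, plus the class log-prior
#' ratio from the class counts. By default the variance is pooled across
#' the two classes (one shared variance per voxel), which makes the
#' discriminant linear in the pattern; `var_mode = "class"` keeps separate
#' per-class variances. Variances are floored at a small positive fraction
#' of the mean training variance so the discriminant stays finite for
#' degenerate voxels.
#'
#' @param x numeric matrix of training samples x cluster voxels.
#' @param labels two-class label per training sample; the first class in
#'   `sort(unique(labels))` is the "positive" class of the discriminant.
#' @param var_mode `"pooled"` (default) or `"class"`.
#' @return an object of class `gnb_model` with fields `mu` (2 x voxels),
#'   `var` (2 x voxels; identical rows under pooling), `log_prior_ratio`
#'   and `classes`.
#' @export
fit_gnb <- function(x, labels, var_mode = c("pooled", "class")) {
  var_mode <- match.arg(var_mode)
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes are required")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) stop("each class needs at least 2 training samples")
  mu <- var <- matrix(0, 2L, ncol(x))
  for (c in 1:2) {
    xc <- x[labels == classes[c], , drop = FALSE]
    mu[c, ] <- colMeans(xc)
    var[c, ] <- colMeans(sweep(xc, 2L, mu[c, ])^2)  # ML (biased) variance
  }
  if (var_mode == "pooled") {
    pooled <- (counts[[1L]] * var[1L, ] + counts[[2L]] * var[2L, ]) /
      sum(counts)
    var <- rbind(pooled, pooled)
  }
  floor_ <- 1e-8 * (mean(var) + 1e-12)
  var <- pmax(var, floor_)
  structure(list(mu = mu, var = var,
                 log_prior_ratio = log(counts[[1L]] / counts[[2L]]),
                 classes = classes, var_mode = var_mode),
            class = "gnb_model")
}

#' Gaussian naive Bayes discriminant
#'
#' The two-class log-posterior-odds under the fitted per-voxel Gaussian
#' class-conditional densities: the class log-prior ratio plus the sum over
#' voxels of the log-density difference. Positive values favor the model's
#' first class.
#'
#' @param model a [fit_gnb()] model.
#' @param x numeric matrix of samples x cluster voxels (or a single pattern
#'   vector).
#' @return numeric vector of discriminants, one per sample.
#' @export
gnb_discriminant <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model$mu))
    stop("pattern does not cover the model's voxels")
  ll <- function(c) {
    d <- sweep(x, 2L, model$mu[c, ])
    -0.5 * sweep(d^2, 2L, model$var[c, ], "/") -
      matrix(0.5 * log(2 * pi * model$var[c, ]), nrow(x), ncol(x),
             byrow = TRUE)
  }
  as.numeric(model$log_prior_ratio) + rowSums(ll(1L) - ll(2L))
}

#' Multivariate within-cluster summarization (mMIC)
#'
#' Fits one Gaussian naive Bayes model per cluster on the training patterns
#' only, then replaces each cluster's multi-voxel pattern by its GNB
#' discriminant in both the training and the test set. The test set never
#' influences the fitted models.
#'
#' @param train,test voxel-feature [mic_patterns()] sharing one feature map.
#' @param partition a [mic_partition()] over the same voxels.
#' @param var_mode variance estimation mode, see [fit_gnb()].
#' @return list of two cluster-feature [mic_patterns()]: `train` and `test`.
#' @export
summarize_mmic <- function(train, test, partition,
                           var_mode = c("pooled", "class")) {
  var_mode <- match.arg(var_mode)
  check_partition_features(train, partition)
  if (!identical(train$feature_map, test$feature_map))
    stop("train and test pattern sets must share a feature map")
  n_cl <- length(partition$clusters)
  xtr <- matrix(0, nrow(train$x), n_cl)
  xte <- matrix(0, nrow(test$x), n_cl)
  for (h in seq_len(n_cl)) {
    cols <- match(partition$clusters[[h]], train$feature_map)
    model <- fit_gnb(train$x[, cols, drop = FALSE], train$labels, var_mode)
    xtr[, h] <- gnb_discriminant(model, train$x[, cols, drop = FALSE])
    xte[, h] <- gnb_discriminant(model, test$x[, cols, drop = FALSE])
  }
  list(train = mic_patterns(xtr, train$labels, train$runs, "cluster",
                            seq_len(n_cl)),
       test = mic_patterns(xte, test$labels, test$runs, "cluster",
                           seq_len(n_cl)))
}
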