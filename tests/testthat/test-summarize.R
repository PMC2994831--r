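make_partition <- function(clusters, n_vox) {
  mic_partition(clusters, setdiff(seq_len(n_vox), unlist(clusters)),
                2L, "face", n_vox)
}

test_that("uMIC is the within-cluster spatial mean", {
  x <- rbind(c(1, 2, 3, 10), c(4, 5, 6, 20))
  p <- mic_patterns(x, c(1L, 2L), c(1L, 1L))
  part <- make_partition(list(1:3, 4L), 4L)
  out <- summarize_umic(p, part)
  expect_equal(out$x, cbind(c(2, 5), c(10, 20)))
  expect_equal(out$feature_kind, "cluster")
  # brute-force oracle on random data
  set.seed(5)
  xr <- matrix(rnorm(60), 6L, 10L)
  pr <- mic_patterns(xr, rep(1:2, 3), rep(1:3, each = 2))
  partr <- make_partition(list(c(1L, 4L, 9L), c(2L, 3L)), 10L)
  outr <- summarize_umic(pr, partr)
  brute <- cbind(rowMeans(xr[, c(1, 4, 9)]), rowMeans(xr[, c(2, 3)]))
  expect_equal(outr$x, brute, tolerance = 1e-12)
})

test_that("uMIC is linear in its input", {
  set.seed(6)
  x <- matrix(rnorm(40), 4L, 10L)
  p <- function(m) mic_patterns(m, rep(1:2, 2), rep(1:2, each = 2))
  part <- make_partition(list(1:4, 5:7), 10L)
  expect_equal(summarize_umic(p(3 * x + 2), part)$x,
               3 * summarize_umic(p(x), part)$x + 2, tolerance = 1e-12)
})

test_that("GNB fitting recovers hand-computed means and ML variances", {
  x <- matrix(c(0, 2, -1, 1), 4L, 1L)
  m <- fit_gnb(x, c(1L, 1L, 2L, 2L))
  expect_equal(m$mu[, 1L], c(1, 0))
  expect_equal(unname(m$var[, 1L]), c(1, 1))  # ML variance; pooled = 1 too
  expect_equal(as.numeric(m$log_prior_ratio), 0)
  # per-class mode keeps distinct variances
  x2 <- matrix(c(0, 4, -1, 1), 4L, 1L)
  m2 <- fit_gnb(x2, c(1L, 1L, 2L, 2L), var_mode = "class")
  expect_equal(unname(m2$var[, 1L]), c(4, 1))
  expect_equal(unname(fit_gnb(x2, c(1L, 1L, 2L, 2L))$var[, 1L]), c(2.5, 2.5))
})

test_that("GNB degenerate cases: identical classes, variance floor, errors", {
  x <- matrix(c(1, 3, 1, 3), 4L, 1L)
  m <- fit_gnb(x, c(1L, 1L, 2L, 2L))  # identical training data per class
  expect_equal(m$mu[1L, ], m$mu[2L, ])
  expect_equal(m$var[1L, ], m$var[2L, ])
  expect_equal(gnb_discriminant(m, matrix(5)), 0)  # symmetric classes
  const <- matrix(2, 4L, 1L)
  mc <- fit_gnb(const, c(1L, 1L, 2L, 2L))
  expect_gt(mc$var[1L, 1L], 0)  # floor engaged
  expect_error(fit_gnb(x, c(1L, 2L, 2L, 2L)), "at least 2")
  expect_error(fit_gnb(x, rep(1L, 4L)), "two classes")
})

test_that("the discriminant is the joint Gaussian log-odds", {
  # one voxel, mu = +-1, unit variances, equal priors
  m <- structure(list(mu = matrix(c(1, -1), 2L, 1L),
                      var = matrix(1, 2L, 1L),
                      log_prior_ratio = 0, classes = 1:2),
                 class = "gnb_model")
  expect_equal(gnb_discriminant(m, matrix(0)), 0)
  expect_equal(gnb_discriminant(m, matrix(1)), 2)
  expect_error(gnb_discriminant(m, matrix(1, 1L, 2L)), "cover")
  # random small models vs density-product oracle
  set.seed(9)
  for (rep in 1:20) {
    p <- sample(1:5, 1L)
    n <- 8L
    x <- matrix(rnorm(n * p), n, p)
    labels <- rep(1:2, each = 4L)
    mode <- sample(c("pooled", "class"), 1L)
    mod <- fit_gnb(x, labels, mode)
    xn <- rnorm(p)
    expect_equal(gnb_discriminant(mod, xn), gnb_oracle(mod, xn),
                 tolerance = 1e-10)
  }
})

test_that("mMIC fits on training data only and detects mean shifts", {
  set.seed(10)
  n <- 16L
  x <- matrix(rnorm(n * 6L), n, 6L)
  labels <- rep(1:2, each = 8L)
  x[labels == 1L, 1:3] <- x[labels == 1L, 1:3] + 3
  tr <- mic_patterns(x, labels, rep(1:4, 4L))
  te1 <- mic_patterns(matrix(rnorm(4 * 6), 4L), rep(1:2, 2), rep(5L, 4L))
  te2 <- mic_patterns(matrix(rnorm(4 * 6, 10), 4L), rep(1:2, 2), rep(5L, 4L))
  part <- make_partition(list(1:3, 4:6), 6L)
  out1 <- summarize_mmic(tr, te1, part)
  out2 <- summarize_mmic(tr, te2, part)
  # test data never influence the fitted models
  expect_equal(out1$train$x, out2$train$x)
  # informative cluster: class-1 training discriminants mostly positive,
  # sign agrees with the per-sample density-ratio oracle
  expect_gt(mean(out1$train$x[labels == 1L, 1L] > 0), 0.8)
  expect_gt(mean(out1$train$x[labels == 2L, 1L] < 0), 0.8)
})

test_that("single-voxel clusters reduce mMIC to per-voxel log-odds", {
  set.seed(11)
  x <- matrix(rnorm(12L * 2L), 12L)
  labels <- rep(1:2, 6L)
  tr <- mic_patterns(x, labels, rep(1:3, each = 4L))
  part <- make_partition(list(1L, 2L), 2L)
  out <- summarize_mmic(tr, tr, part)
  for (v in 1:2) {
    mod <- fit_gnb(x[, v, drop = FALSE], labels)
    expect_equal(out$train$x[, v], gnb_discriminant(mod, x[, v, drop = FALSE]))
  }
})

test_that("uMIC and mMIC order samples identically for iid voxels", {
  # all voxels of the cluster share one distribution per class and the
  # pooled-variance discriminant is linear in the cluster mean
  set.seed(12)
  n <- 10L
  x0 <- rnorm(n)
  x <- cbind(x0, x0, x0) + matrix(rnorm(3 * n, sd = 1e-8), n)
  labels <- rep(1:2, each = 5L)
  p <- mic_patterns(x, labels, rep(1:5, 2L))
  part <- make_partition(list(1:3), 3L)
  u <- summarize_umic(p, part)$x[, 1L]
  m <- summarize_mmic(p, p, part)$train$x[, 1L]
  # identical ordering up to the discriminant's class orientation
  expect_true(identical(order(u), order(m)) ||
                identical(order(u), order(-m)))
})
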