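test_that("the margin-maximizing separator is found on a 1-D toy", {
  x <- matrix(c(-1, -1, 1, 1), 4L, 1L)
  y <- c(-1, -1, 1, 1)
  m <- train_linear_svm(x, y, C = 100)
  expect_equal(m$w, 1, tolerance = 1e-5)
  expect_equal(m$b, 0, tolerance = 1e-5)
  expect_equal(unname(predict(m, x)), y)
})

test_that("duplicated feature columns share the weight", {
  set.seed(14)
  x1 <- matrix(rnorm(20), 10L, 2L)
  y <- rep(c(1, -1), 5L)
  m <- train_linear_svm(cbind(x1, x1[, 1L]), y, C = 1)
  expect_equal(m$w[1L] , m$w[3L], tolerance = 1e-6)
})

test_that("the solution matches an enumerative QP oracle on small toys", {
  set.seed(15)
  for (rep in 1:12) {
    n <- sample(4:6, 1L)
    d <- sample(1:2, 1L)
    X <- matrix(rnorm(n * d), n, d)
    y <- c(rep(1, 2), rep(-1, 2), sample(c(-1, 1), n - 4L, replace = TRUE))
    C <- sample(c(0.5, 1, 10), 1L)
    m <- train_linear_svm(X, y, C, tolerance = 1e-11)
    oracle <- qp_svm_oracle(X, y, C)
    obj_pkg <- svm_primal_objective(m$w, m$b, X, y, C)
    # strong duality: at the optimum the primal equals the dual objective
    expect_gte(obj_pkg, oracle$dual_objective - 1e-6)
    expect_lt(obj_pkg - oracle$dual_objective, 1e-6)
  }
})

test_that("decision values and the sign convention behave", {
  x <- matrix(c(0, 0, 1, 2, 2, 0, 3, 2), 4L, 2L, byrow = TRUE)
  m <- structure(list(w = c(1, -1), b = 0.5, C = 1,
                      positive_class = 1L, classes = c(1L, 2L)),
                 class = "mic_svm")
  expect_equal(decision_values(m, x), c(0.5, -0.5, 2.5, 1.5))
  expect_equal(unname(predict(m, x)), c(1L, 2L, 1L, 1L))
  # zero decision value maps to the positive class
  expect_equal(unname(predict(m, matrix(c(0.5, 1), 1L))), 1L)
  # negating w and b flips every prediction
  m2 <- m; m2$w <- -m$w; m2$b <- -m$b
  expect_true(all(predict(m2, x) != predict(m, x)))
})

test_that("features rank by |w| with index tie-breaking", {
  m <- structure(list(w = c(0.5, -2, 1)), class = "mic_svm")
  expect_equal(rank_features(m), c(2L, 3L, 1L))
  m_tie <- structure(list(w = c(1, -1, 1)), class = "mic_svm")
  expect_equal(rank_features(m_tie), 1:3)
  set.seed(16)
  w <- rnorm(50)
  m_r <- structure(list(w = w), class = "mic_svm")
  expect_equal(rank_features(m_r), order(abs(w), decreasing = TRUE))
})

test_that("feature levels follow the geometric progression", {
  lv <- feature_levels()
  expect_length(lv, 10L)
  expect_equal(lv[1:3], c(100L, 150L, 225L))
  expect_equal(lv[10L], 3844L)
  expect_true(all(diff(lv) > 0L))
  expect_equal(feature_levels(10, 10 * 2^9, 10), as.integer(10 * 2^(0:9)))
  expect_error(feature_levels(100, 100), "min_voxels")
})

test_that("voxel selection takes the top weights; cluster selection fills", {
  # MIV: top-n by weight, ties to the lower index (sort oracle)
  set.seed(17)
  w <- sample(rep(1:20, 2))
  model <- structure(list(w = w), class = "mic_svm")
  pat <- mic_patterns(matrix(0, 2L, 40L), 1:2, 1:2)
  wm <- voxel_weight_map(model, pat, 40L)
  sel <- select_voxels(wm, 10L)
  ord <- order(-abs(w), seq_along(w))
  expect_equal(sel, sort(ord[1:10]))
  expect_equal(select_voxels(wm, 40L), 1:40)
  expect_error(select_voxels(wm, 41L), "exceeds")
  # MIC: whole clusters then partial fill
  part <- mic_partition(list(1:10, 11:20), integer(0), 2L, "face", 20L)
  cmodel <- structure(list(w = c(2, -1)), class = "mic_svm")
  cpat <- mic_patterns(matrix(0, 2L, 2L), 1:2, 1:2,
                       feature_kind = "cluster", feature_map = 1:2)
  cwm <- voxel_weight_map(cmodel, cpat, 20L, part)
  expect_equal(select_voxels(cwm, 15L), c(1:10, 11:15))
  # weight map is piecewise constant over clusters
  expect_equal(unique(cwm$w[1:10]), 2)
  expect_equal(unique(cwm$w[11:20]), 1)
})

test_that("selections are nested across increasing feature levels", {
  set.seed(18)
  x <- matrix(rnorm(12 * 30), 12L)
  y <- rep(1:2, 6L)
  m <- train_linear_svm(x, y, 1)
  pat <- mic_patterns(x, y, rep(1:6, 2L))
  wm <- voxel_weight_map(m, pat, 30L)
  prev <- integer(0)
  for (n in c(3L, 9L, 15L, 30L)) {
    sel <- select_voxels(wm, n)
    expect_length(sel, n)
    expect_true(all(prev %in% sel))
    prev <- sel
  }
  # scale equivariance of the ranking for a separable problem at large C
  x[y == 1L, 1:3] <- x[y == 1L, 1:3] + 10
  m1 <- train_linear_svm(x, y, 100)
  m2 <- train_linear_svm(2.5 * x, y, 100)
  expect_equal(rank_features(m1)[1:3], rank_features(m2)[1:3])
})
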