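test_that("folds partition runs evenly and reproducibly", {
  f8 <- make_folds(rep(1:8, each = 10L), 4L, seed = 1)
  expect_equal(as.vector(table(f8$assignment)), rep(2L, 4L))
  f12 <- make_folds(1:12, 4L, seed = 1)
  expect_equal(as.vector(table(f12$assignment)), rep(3L, 4L))
  expect_identical(make_folds(1:8, 4L, 5), make_folds(1:8, 4L, 5))
  expect_false(identical(make_folds(1:8, 4L, 5)$assignment,
                         make_folds(1:8, 4L, 6)$assignment))
  expect_error(make_folds(1:3, 4L), "folds")
})

test_that("predictive accuracy counts matches", {
  expect_equal(predictive_accuracy(c(1, 2, 1), c(1, 2, 1)), 1)
  expect_equal(predictive_accuracy(c(1, 2), c(2, 1)), 0)
  expect_equal(predictive_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 1)), 0.75)
  expect_error(predictive_accuracy(integer(0), integer(0)), "non-empty")
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic", {
  # hand example: 6 voxels, 2 informative
  w <- c(5, 1, 4, 2, 2, 0)
  truth <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_auc(w, truth)
  expect_equal(r$auc, mwu_auc(w, truth))
  # endpoints of the curve
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
  # perfect and uninformative rankings
  expect_equal(roc_auc(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))$auc,
               0.5)
  # random instances with heavy ties (cluster-constant maps)
  set.seed(19)
  for (rep in 1:20) {
    w <- sample(0:5, 40L, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), 40L, replace = TRUE, prob = c(0.3, 0.7))
    if (all(truth) || !any(truth)) next
    expect_equal(roc_auc(w, truth)$auc, mwu_auc(w, truth), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("robustness and overlap follow intersection-over-union", {
  expect_equal(robustness(list(1:5, 1:5, 1:5, 1:5)), 1)
  expect_equal(robustness(list(1:2, 3:4, 5:6)), 0)
  expect_equal(robustness(list(c(1, 2), c(2, 3))), 1 / 3)
  expect_equal(overlap_rate(1:100, 51:150), 50 / 150)
  expect_equal(overlap_rate(integer(0), integer(0)), 1)
  expect_equal(overlap_rate(1:3, 1:3), 1)
  expect_equal(overlap_rate(1:3, 4:6), 0)
  # invariance under relabeling of voxel ids
  set.seed(20)
  sets <- replicate(4, sample(1:50, 20), simplify = FALSE)
  perm <- sample(1:50)
  relabeled <- lapply(sets, function(s) perm[s])
  expect_equal(robustness(relabeled), robustness(sets))
  expect_error(robustness(list(1:3)), "two sets")
})

test_that("mapping uses training data only: test labels are irrelevant", {
  sim <- simulate_dataset(tiny_sim_config(seed = 23))
  folds <- make_folds(sim$design$run, 4L, 1)
  r1 <- mic_cv(sim$dataset, sim$design, methods = "mMIC", folds = folds,
               Ts = 8L, levels = c(10L, 30L), truth = sim$truth)
  # shuffle condition labels in the test runs' blocks only
  design2 <- sim$design
  test_runs <- names(folds$assignment)[folds$assignment == 1]
  in_test <- as.character(design2$run) %in% test_runs & design2$condition > 0L
  design2$condition[in_test] <- 3L - design2$condition[in_test]
  r2 <- mic_cv(sim$dataset, design2, methods = "mMIC", folds = folds,
               Ts = 8L, levels = c(10L, 30L), truth = sim$truth)
  # fold 1's mapping never saw its own test runs' labels; for the other
  # folds those runs are training data, so only fold 1 must be unchanged
  expect_equal(r1$mMIC$selected[[1L]], r2$mMIC$selected[[1L]])
  expect_equal(r1$mMIC$fold_auc[1L], r2$mMIC$fold_auc[1L])
})

test_that("the CV harness returns coherent results for all methods", {
  sim <- simulate_dataset(tiny_sim_config(seed = 24))
  res <- mic_cv(sim$dataset, sim$design,
                methods = c("MIV", "MIVs", "uMIC", "mMIC", "mMICc"),
                folds = make_folds(sim$design$run, 4L, 2),
                Ts = 8L, block_dims = c(2L, 2L, 2L),
                levels = c(20L, 60L, 120L), truth = sim$truth)
  for (m in names(res)) {
    r <- res[[m]]
    expect_true(all(r$fold_acc >= 0 & r$fold_acc <= 1))
    expect_equal(dim(r$fold_acc), c(4L, length(r$levels)))
    expect_equal(r$max_accuracy, max(colMeans(r$fold_acc)))
    expect_true(all(r$level_robustness >= 0 & r$level_robustness <= 1))
    expect_length(r$fold_auc, 4L)
    for (f in 1:4)
      expect_equal(lengths(r$selected[[f]]), r$levels)
  }
  # separable regime: strong signal is decoded perfectly at some level
  expect_gte(res$mMIC$max_accuracy, res$uMIC$max_accuracy - 0.3)
})

test_that("a perfectly separable pattern set is classified perfectly", {
  set.seed(25)
  n_vox <- 60L
  shape <- c(60L, 1L, 1L)
  n_vol <- 80L
  run_ids <- rep(1:4, each = 20L)
  cond <- rep(rep(c(0L, 1L, 0L, 2L, 0L), each = 4L), 4L)
  design <- data.frame(run = run_ids, volume = sequence(rep(20L, 4L)) - 1L,
                       condition = cond)
  class(design) <- c("mic_design", "data.frame")
  vals <- matrix(rnorm(n_vox * n_vol, sd = 0.01), n_vox, n_vol)
  vals[1:10, cond == 1L] <- vals[1:10, cond == 1L] + 100
  ds <- grid_dataset(vals, shape, run_ids = run_ids)
  res <- mic_cv(ds, design, methods = "MIV",
                folds = make_folds(run_ids, 4L, 1),
                levels = c(10L, 30L, 60L), shift_volumes = 0L)
  expect_equal(res$MIV$max_accuracy, 1)
  expect_true(all(res$MIV$fold_acc == 1))
})
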