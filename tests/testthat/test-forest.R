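test_that("a constant response yields single-leaf trees predicting it", {
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- rep(2.5, 30)
  fit <- suppressWarnings(grow_forest(X, y, forest_control(ntree = 10, seed = 1)))
  expect_true(all(vapply(fit$trees, nrow, integer(1)) == 1L))
  expect_equal(unname(predict(fit, X)), rep(2.5, 30))
  expect_warning(grow_forest(X, y, forest_control(ntree = 5, seed = 1)),
                 "single leaf")
})

test_that("the root split of a step function matches the exhaustive scan", {
  set.seed(6)
  x <- runif(50, -1, 1)
  y <- as.numeric(x > 0) + rnorm(50, sd = 0.01)
  fit <- grow_forest(matrix(x, ncol = 1), y,
                     forest_control(ntree = 25, mtry = 1, min_node = 5,
                                    seed = 3))
  for (t in seq_len(25)) {
    boot <- rep(seq_along(x), fit$inbag[, t])
    expect_equal(unname(fit$trees[[t]][1, "split"]),
                 best_split_oracle(x[boot], y[boot]))
  }
})

test_that("the out-of-bag fraction concentrates near 1/e", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- rnorm(200)
  fit <- grow_forest(X, y, forest_control(ntree = 200, seed = 8))
  frac <- mean(colSums(fit$inbag == 0)) / 200
  expect_gt(frac, 0.33)
  expect_lt(frac, 0.41)
})

# hand-built depth-1 stump for exact OOB traversal checks
make_stump_model <- function() {
  tree <- cbind(var = c(1, 0, 0), split = c(0, 0, 0),
                left = c(2, 0, 0), right = c(3, 0, 0),
                pred = c(0, -1, 1), n = c(6, 3, 3))
  inbag <- matrix(1L, 6, 1)
  inbag[3:6, 1] <- 0L  # rows 3..6 are out of bag
  structure(list(trees = list(tree), inbag = inbag, n = 6, p = 2, mtry = 1,
                 feature_names = c("x1", "x2"),
                 control = forest_control(ntree = 1)),
            class = "screen_rf")
}

test_that("OOB predictions trace the tree, with and without permutation", {
  model <- make_stump_model()
  X <- cbind(c(1, -1, -2, -0.5, 0.5, 2), rnorm(6))
  base <- predict_oob(model, X, tree = 1)
  expect_identical(names(base), c("3", "4", "5", "6"))
  expect_equal(unname(base), c(-1, -1, 1, 1))  # sign of x1 decides the leaf
  # identity permutation reproduces the unpermuted predictions
  expect_equal(predict_oob(model, X, 1, feature = 1, perm = 1:4), base)
  # reversing the OOB values of x1 flips each prediction
  rev_pred <- predict_oob(model, X, 1, feature = 1, perm = 4:1)
  expect_equal(unname(rev_pred), c(1, 1, -1, -1))
  # permuting a feature the tree never uses changes nothing
  expect_equal(predict_oob(model, X, 1, feature = 2, perm = c(2, 3, 4, 1)),
               base)
})

test_that("PVIM is exactly zero for features no tree splits on", {
  set.seed(15)
  n <- 80
  X <- cbind(rnorm(n), rnorm(n), rnorm(n), rep(1, n))  # x4 constant
  y <- 2 * X[, 1] + rnorm(n, sd = 0.2)
  fit <- grow_forest(X, y, forest_control(ntree = 50, mtry = 4, seed = 4))
  imp <- pvim(fit, X, y, keep_per_tree = TRUE)
  expect_identical(unname(imp$importance[4]), 0)
  expect_true(all(imp$per_tree[, 4] == 0))
  # the per-tree average identity
  expect_equal(unname(colMeans(imp$per_tree)), unname(imp$importance))
})

test_that("PVIM is positive for true signal and centered for pure noise", {
  signal <- numeric(20)
  noise <- numeric(20)
  for (r in 1:20) {
    set.seed(1000 + r)
    n <- 60
    X <- matrix(rnorm(n * 5), n, 5)
    y <- X[, 1] + rnorm(n, sd = 0.5)
    fit <- grow_forest(X, y, forest_control(ntree = 100, seed = r))
    imp <- pvim(fit, X, y, permutation_seed = 5000 + r)$importance
    signal[r] <- imp[1]
    noise[r] <- imp[5]
  }
  expect_true(all(signal > 0))
  # pure-noise importance within 3 standard errors of zero
  expect_lt(abs(mean(noise)) / (sd(noise) / sqrt(20)), 3)
})

test_that("forest fitting and PVIM are bit-reproducible under fixed seeds", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- X[, 2] + rnorm(60)
  ctl <- forest_control(ntree = 40, seed = 11)
  f1 <- grow_forest(X, y, ctl)
  f2 <- grow_forest(X, y, ctl)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(pvim(f1, X, y, permutation_seed = 2)$importance,
                   pvim(f2, X, y, permutation_seed = 2)$importance)
  expect_false(identical(pvim(f1, X, y, permutation_seed = 3)$importance,
                         pvim(f1, X, y, permutation_seed = 2)$importance))
})

test_that("splits never increase the within-node squared error", {
  set.seed(19)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- X[, 1] * X[, 2] + rnorm(100)
  fit <- grow_forest(X, y, forest_control(ntree = 5, seed = 21))
  for (t in 1:5) {
    w <- fit$inbag[, t]
    pred <- predict(fit, X, trees = t)
    boot_mean <- sum(w * y) / sum(w)
    expect_lte(sum(w * (y - pred)^2), sum(w * (y - boot_mean)^2))
  }
})

test_that("more trees stabilize the importance estimate", {
  set.seed(301)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- X[, 1] + rnorm(60, sd = 0.5)
  vimp <- sapply(c(50, 500), function(nt) {
    sapply(1:10, function(r) {
      fit <- grow_forest(X, y, forest_control(ntree = nt, seed = r))
      pvim(fit, X, y, permutation_seed = 900 + r)$importance[1]
    })
  })
  # on fixed data, refit-to-refit spread is ensemble noise only and must
  # shrink as the ensemble grows
  expect_lt(var(vimp[, 2]), var(vimp[, 1]))
})

test_that("RF ranking puts a dominant linear signal first", {
  set.seed(33)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- 3 * X[, 1] + rnorm(100, sd = 0.1)
  rk <- rf_ranking(X, y, forest_control(ntree = 100, seed = 2))
  expect_equal(rk$order[1], 1L)
  expect_permutation(rk$order, 10)
})

test_that("PVIM agrees with an independent forest implementation's ordering", {
  skip_if_not_installed("randomForest")
  set.seed(55)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8)
  y <- X[, 1] + 2 * X[, 2] + 1.5 * X[, 3] * X[, 4] + rnorm(n, sd = 0.5)
  mine <- pvim(grow_forest(X, y, forest_control(ntree = 300, seed = 5)),
               X, y)$importance
  rf <- randomForest::randomForest(X, y, ntree = 300, importance = TRUE)
  theirs <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  expect_gt(cor(mine, theirs, method = "spearman"), 0.7)
  expect_equal(unname(which.max(mine)), unname(which.max(theirs)))
})

test_that("impurity importance accumulates split gains and credits signal", {
  set.seed(71)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- 2 * X[, 1] + rnorm(100, sd = 0.3)
  fit <- grow_forest(X, y, forest_control(ntree = 60, seed = 9))
  imp <- impurity_importance(fit)
  expect_true(all(imp >= 0))
  expect_equal(unname(which.max(imp)), 1L)
  # per-tree decomposition check against a direct SSE computation on one stump
  model <- make_stump_model()
  Xs <- cbind(c(1, -1, -2, -0.5, 0.5, 2), rnorm(6))
  g <- impurity_importance(model)
  # stump: n=6 pred 0 split into two leaves of 3 with preds -1, 1
  expect_equal(unname(g), c(3 * 1 + 3 * 1 - 6 * 0, 0))
})
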