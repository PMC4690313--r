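test_that("column standardization centers, scales, and rejects constants", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  Z <- standardize_columns(X)
  expect_equal(unname(colMeans(Z)), c(0, 0))
  expect_equal(unname(apply(Z, 2, var)), c(1, 1))
  expect_equal(standardize_columns(Z), Z)  # idempotent
  expect_error(standardize_columns(cbind(ok = 1:3, bad = c(5, 5, 5))),
               "bad")
})

test_that("SIS scores are |X'y| on standardized columns", {
  set.seed(31)
  X <- matrix(rnorm(25 * 4), 25, 4)
  y <- X[, 3]
  w <- sis_scores(X, y)
  expect_equal(unname(which.max(w)), 3L)

  # brute-force dot products on a hand-standardized 5 x 2 matrix
  X2 <- cbind(c(1, 4, 2, 8, 5), c(3, 1, 4, 1, 5))
  y2 <- c(2, 1, 0, 1, 2)
  Xs <- apply(X2, 2, function(col) (col - mean(col)) / sd(col))
  manual <- c(abs(sum(Xs[, 1] * y2)), abs(sum(Xs[, 2] * y2)))
  expect_equal(unname(sis_scores(X2, y2)), manual)
})

test_that("SIS ranking equals the absolute-Pearson-correlation ranking", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- rnorm(20)
    rk <- scores_to_ranking(sis_scores(X, y))
    expect_identical(rk$order, pearson_rank_oracle(X, y))
    expect_permutation(rk$order, 10)
  }
})

# Construction with a feature that is marginally uncorrelated with y but
# jointly informative: x2 has cor(x1, x2) = -0.7 and y = x1 + 0.7 x2, so
# cov(y, x2) = 0.7 - 0.7 = 0 while conditioning on x1 exposes x2.
make_joint_data <- function(n = 1000, seed = 17) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  x1 <- z1
  x2 <- -0.7 * z1 + sqrt(1 - 0.49) * z2
  y <- x1 + 0.7 * x2 + rnorm(n, sd = 0.1)
  x3 <- 0.2 * y + rnorm(n)  # modest marginal signal, beats x2 marginally
  list(X = cbind(x1 = x1, x2 = x2, x3 = x3), y = y)
}

test_that("ISIS recovers jointly-but-not-marginally correlated features", {
  dat <- make_joint_data()
  sis_rk <- scores_to_ranking(sis_scores(dat$X, dat$y))
  isis_rk <- isis_ranking(dat$X, dat$y, d = 2, step_size = 1)
  expect_equal(unname(sis_rk$ranks["x2"]), 3L)   # invisible marginally
  expect_equal(unname(isis_rk$ranks["x2"]), 2L)  # enters after x1
  expect_equal(isis_rk$order[1], 1L)
  expect_lte(isis_rk$ranks["x2"], sis_rk$ranks["x2"])
})

test_that("iteration 1 of the iterative screeners is the marginal screen", {
  set.seed(41)
  X <- matrix(rnorm(60 * 12), 60, 12)
  y <- 2 * X[, 1] + X[, 5] + rnorm(60)
  top3 <- scores_to_ranking(sis_scores(X, y))$order[1:3]
  expect_identical(isis_ranking(X, y, d = 6, step_size = 3)$order[1:3], top3)

  u <- runif(60)
  cc_top <- scores_to_ranking(conditional_correlation_scores(X, y, u))$order[1:3]
  expect_identical(iccsis_ranking(X, y, u, d = 6, step_size = 3)$order[1:3],
                   cc_top)
})

test_that("distance correlation matches its definition", {
  set.seed(7)
  a <- rnorm(15)
  expect_equal(distance_correlation(a, a), 1)
  expect_equal(distance_correlation(a, rep(2, 15)), 0)
  expect_equal(distance_correlation(1:4, c(2, 4, 6, 8)), 1)
  expect_equal(distance_correlation(c(0, 1, 2), c(0, 1, 4)),
               dcor_oracle(c(0, 1, 2), c(0, 1, 4)))
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(distance_correlation(x, y), dcor_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(distance_correlation(1, 1), "at least 2")
  expect_error(distance_correlation(1:3, 1:4), "equal length")
})

test_that("distance correlation is symmetric and affine-invariant", {
  set.seed(12)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(distance_correlation(a, b), distance_correlation(b, a))
  expect_equal(distance_correlation(3 * a + 2, b), distance_correlation(a, b),
               tolerance = 1e-10)
  expect_equal(distance_correlation(a, 0.5 * b - 7), distance_correlation(a, b),
               tolerance = 1e-10)
})

test_that("sample dcorr grows with the underlying normal correlation", {
  n <- 2000
  vals <- vapply(c(0, 0.3, 0.6, 0.9), function(r) {
    set.seed(100)
    z1 <- rnorm(n); z2 <- rnorm(n)
    distance_correlation(z1, r * z1 + sqrt(1 - r^2) * z2)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("DC-SIS sees nonlinear signal that Pearson misses", {
  set.seed(23)
  X <- matrix(rnorm(300 * 6), 300, 6)
  y <- X[, 1]^2 + 0.2 * rnorm(300)
  w <- dcsis_scores(X, y)
  expect_equal(unname(which.max(w)), 1L)
  expect_lt(abs(cor(X[, 1], y)), 0.15)  # the marginal screen is blind here
})

test_that("conditional correlation screening handles exact and functional signal", {
  set.seed(9)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10)
  u <- runif(n)
  y <- X[, 1]
  w <- conditional_correlation_scores(X, y, u)
  expect_equal(unname(which.max(w)), 1L)
  expect_gt(w[1], 0.95)

  # varying-coefficient signal: y = u * x1 + noise
  y2 <- u * X[, 1] + rnorm(n)
  w2 <- conditional_correlation_scores(X, y2, u)
  expect_gt(w2[1], median(w2[-1]))

  expect_error(conditional_correlation_scores(X, y, u, bandwidth = 0),
               "bandwidth")
  expect_error(conditional_correlation_scores(X, y, u - 2), "\\[0, 1\\]")
})

test_that("a constant covariate reduces the conditional screen to the marginal one", {
  set.seed(13)
  X <- matrix(rnorm(80 * 8), 80, 8)
  y <- X[, 2] + 0.5 * X[, 6] + rnorm(80)
  u0 <- rep(0.5, 80)
  cc <- scores_to_ranking(conditional_correlation_scores(X, y, u0,
                                                         bandwidth = 1))
  expect_identical(cc$order, pearson_rank_oracle(X, y))
  icc <- iccsis_ranking(X, y, u0, d = 6, step_size = 2, bandwidth = 1)
  isis <- isis_ranking(X, y, d = 6, step_size = 2)
  expect_identical(icc$order, isis$order)
})

test_that("score-to-ranking conversion is deterministic with indexed ties", {
  r <- scores_to_ranking(c(0.1, 0.9, 0.5))
  expect_identical(r$order, c(2L, 3L, 1L))
  expect_identical(scores_to_ranking(c(0.5, 0.5))$order, c(1L, 2L))
  expect_error(scores_to_ranking(c(1, NaN, 2)), "feature 2")
  for (s in 1:5) {
    set.seed(s)
    sc <- rnorm(50)
    rk <- scores_to_ranking(sc)
    expect_identical(rk$ranks[rk$order], stats::setNames(1:50, NULL)[1:50])
    expect_permutation(rk$order, 50)
  }
})

test_that("every screening method returns a full permutation ranking", {
  set.seed(77)
  n <- 50; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] + X[, 2] * X[, 3] + rnorm(n)
  u <- runif(n)
  ctl <- forest_control(ntree = 30, seed = 2)
  for (m in c("sis", "isis", "ccsis", "iccsis", "dcsis", "rf")) {
    rk <- screen_features(X, y, u, method = m, d = 10, control = ctl)
    expect_permutation(rk$order, p)
    expect_identical(unname(rk$ranks[rk$order]), 1:p)
  }
})
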