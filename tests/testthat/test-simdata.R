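test_that("AR(1) covariance has rho^|i-j| entries and stays positive definite", {
  S <- ar1_covariance(3, 0.4)
  expect_equal(S, rbind(c(1, 0.4, 0.16),
                        c(0.4, 1, 0.4),
                        c(0.16, 0.4, 1)))
  expect_equal(ar1_covariance(4, 0), diag(4))
  expect_gt(min(eigen(ar1_covariance(5, 0.9), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  for (rho in c(0.4, 0.95)) {
    S <- ar1_covariance(200, rho)
    expect_identical(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(ar1_covariance(3, 1), "rho")
  expect_error(ar1_covariance(3, -0.1), "rho")
})

test_that("feature generation matches the designed correlation structure", {
  d <- sim_design("sim1", n = 5000, p = 3, rho = 0.4, causal = 1:3)
  X <- generate_features(d, seed = 11)$X
  expect_null(generate_features(d, seed = 11)$u)
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.4), 0.03)
  expect_lt(abs(cor(X[, 1], X[, 3]) - 0.16), 0.03)
  # column moments converge to the standard normal's
  expect_lt(max(abs(colMeans(X))), 3 / sqrt(5000))
  expect_lt(max(abs(apply(X, 2, var) - 1)), 3 / sqrt(5000))
})

test_that("the covariate u is uniform and AR(1)-correlated with the features", {
  d <- sim_design("sim3", n = 5000, p = 6, rho = 0.4)
  feat <- generate_features(d, seed = 5)
  u <- feat$u
  expect_true(all(u > 0 & u < 1))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  # correlation with x_j decays in j (u* leads the AR(1) chain)
  expect_gt(cor(u, feat$X[, 1]), cor(u, feat$X[, 4]) + 0.1)
})

test_that("coefficient values reproduce the four designs' formulas", {
  expect_equal(coefficient_values("sim1"), c(0.5, 0.8, 1, 2))
  expect_equal(coefficient_values("sim2"), c(2, 3, 4))
  b3 <- coefficient_values("sim3", u = 0)
  expect_equal(unname(drop(b3)), c(3, 1.5, 1, 3))
  b4 <- coefficient_values("sim4", u = 1)
  expect_equal(unname(b4[, "b2"]), 0)
  expect_equal(unname(b4[, "b3"]), 3)
  expect_error(coefficient_values("sim3"), "requires u")
  # per-observation rows for functional designs
  expect_equal(dim(coefficient_values("sim4", u = c(0, 0.5, 1))), c(3, 3))
})

test_that("responses follow the two structural equations", {
  ones <- matrix(1, 1, 5)
  expect_equal(generate_response(ones, "sim1", epsilon = 0), 4.3)
  expect_equal(generate_response(ones, "sim2", epsilon = 0), 9)
  expect_equal(generate_response(ones, "sim3", u = 0, epsilon = 0), 8.5)
  expect_error(generate_response(matrix(1, 1, 4), "sim1", epsilon = 0),
               "5 columns")
  # signal variance on top of unit noise
  d <- sim_design("sim1", n = 200, p = 10)
  rep1 <- generate_replicate(d, seed = 3)
  expect_gt(var(rep1$y), 2)
})

test_that("replicate generation is reproducible and seed-sensitive", {
  d <- sim_design("sim1", n = 40, p = 10)
  a <- generate_replicate(d, seed = 1)
  b <- generate_replicate(d, seed = 1)
  expect_identical(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, generate_replicate(d, seed = 2)$y))
  expect_identical(a$causal, 1:5)

  reps <- simulate_replicates(d, 5, master_seed = 9)
  reps2 <- simulate_replicates(d, 5, master_seed = 9)
  expect_identical(lapply(reps, `[[`, "y"), lapply(reps2, `[[`, "y"))
  seeds <- vapply(reps, `[[`, integer(1), "seed")
  expect_equal(length(unique(seeds)), 5)

  d3 <- sim_design("sim3", n = 30, p = 8)
  r3 <- generate_replicate(d3, seed = 4)
  expect_length(r3$u, 30)
  expect_true(all(r3$u >= 0 & r3$u <= 1))
})
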