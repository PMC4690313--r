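#' Simulation design for the screening benchmark
#'
#' Describes one of the four synthetic settings used to compare screening
#' methods.  Features are jointly Gaussian with an AR(1) correlation
#' structure (`cor(x_i, x_j) = rho^|i-j|`), the first five features are
#' causal, and the continuous response mixes linear, quadratic and product
#' (epistasis-like) terms:
#'
#' * `sim1`: `y = 0.5 x1 + 0.8 x2 + x3 + 2 x4 x5 + e` (linear + one
#'   interaction, constant coefficients),
#' * `sim2`: `y = 2 x1^2 + 3 x2 x3 + 4 x4 x5 + e` (nonlinear + two
#'   interactions, constant coefficients),
#' * `sim3` / `sim4`: the same two response forms but with coefficients
#'   that are smooth functions of a covariate `u` correlated with the
#'   features (see [coefficient_values()]).
#'
#' For `sim3`/`sim4` the covariate arises as `u = pnorm(u*)` where
#' `(u*, X)` is drawn jointly from a `(p+1)`-dimensional AR(1) Gaussian
#' with `u*` in the first coordinate, so `u` is Uniform(0,1) marginally and
#' `cor(u*, x_j) = rho^j`.
#'
#' @param design which of the four designs to simulate.
#' @param n sample size (the benchmark uses 200).
#' @param p number of features (the benchmark uses 1000).
#' @param rho AR(1) correlation parameter in `[0, 1)` (the benchmark uses 0.4).
#' @param causal indices of the truly associated features; the response
#'   formulas use the first five, so the default is `1:5`.
#' @return An object of class `"sim_design"`.
#' @seealso [generate_replicate()], [simulate_replicates()]
#' @examples
#' d <- sim_design("sim1", n = 50, p = 20)
#' rep1 <- generate_replicate(d, seed = 1)
#' dim(rep1$X)
#' @export
sim_design <- function(design = c("sim1", "sim2", "sim3", "sim4"),
                       n = 200, p = 1000, rho = 0.4, causal = 1:5) {
  design <- match.arg(design)
  n <- as.integer(n)
  p <- as.integer(p)
  causal <- sort(unique(as.integer(causal)))
  if (n < 2) stop("n must be at least 2")
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  if (length(causal) == 0 || any(causal < 1)) stop("causal indices must be positive")
  if (p < max(causal)) stop("p must be at least max(causal)")
  structure(list(design = design, n = n, p = p, rho = rho, causal = causal),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design ", x$design, ": n = ", x$n, ", p = ", x$p,
      ", rho = ", x$rho, "\n", sep = "")
  cat("  causal features:", paste(x$causal, collapse = ", "), "\n")
  if (design_has_u(x$design))
    cat("  includes covariate u = pnorm(u*), u* leading an AR(1) chain with X\n")
  invisible(x)
}

design_has_u <- function(design) design %in% c("sim3", "sim4")

#' AR(1) covariance matrix
#'
#' Entry `(i, j)` equals `rho^|i-j|`; the diagonal is 1 and the matrix is
#' positive definite for any `rho` in `[0, 1)`.
#'
#' @param p dimension.
#' @param rho AR(1) parameter in `[0, 1)`.
#' @return A `p x p` symmetric matrix.
#' @examples
#' ar1_covariance(3, 0.4)
#' @export
ar1_covariance <- function(p, rho) {
  if (!is.numeric(p) || length(p) != 1 || p < 1) stop("p must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  p <- as.integer(p)
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

# Cholesky factor of the design's sampling covariance (p, or p+1 when the
# design carries the covariate u* in the leading coordinate).  Benchmarks
# reuse it across replicates: at p = 1000 the factorisation dominates a
# single replicate's cost.
design_cholesky <- function(design) {
  d <- design$p + if (design_has_u(design$design)) 1L else 0L
  chol(ar1_covariance(d, design$rho))
}

#' Draw the feature matrix (and covariate) of one replicate
#'
#' Samples `n` rows from `N(0, Sigma)` with `Sigma = ar1_covariance(p, rho)`
#' via the (upper-triangular) Cholesky factor.  For designs `sim3`/`sim4`,
#' `(u*, X)` is drawn jointly from the `(p+1)`-dimensional AR(1) Gaussian
#' and the covariate returned is `u = pnorm(u*)`.
#'
#' @param design a [sim_design()] object.
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @param chol_factor optional precomputed [design_cholesky] factor (an
#'   upper-triangular matrix); supplied by [simulate_replicates()] to avoid
#'   refactorising per replicate.
#' @return A list with elements `X` (an `n x p` matrix with columns named
#'   `x1..xp`) and `u` (length-`n` vector in (0,1), or `NULL` for
#'   `sim1`/`sim2`).
#' @export
generate_features <- function(design, seed, chol_factor = NULL) {
  stopifnot(inherits(design, "sim_design"))
  d <- design$p + if (design_has_u(design$design)) 1L else 0L
  if (is.null(chol_factor)) {
    chol_factor <- design_cholesky(design)
  } else if (!is.matrix(chol_factor) || nrow(chol_factor) != d) {
    stop("chol_factor has the wrong dimension for this design")
  }
  set.seed(seed)
  Z <- matrix(rnorm(design$n * d), design$n, d)
  M <- Z %*% chol_factor
  if (design_has_u(design$design)) {
    u <- pnorm(M[, 1])
    X <- M[, -1, drop = FALSE]
  } else {
    u <- NULL
    X <- M
  }
  colnames(X) <- paste0("x", seq_len(design$p))
  list(X = X, u = u)
}

#' Regression coefficients of the four simulation designs
#'
#' Constant-coefficient designs return a plain numeric vector; the
#' functional-coefficient designs return one coefficient vector per
#' observation (a matrix with `length(u)` rows), with
#'
#' * `sim3`: `b1 = 2 + (u+1)^3`, `b2 = (2u^2+3)/2`, `b3 = exp(4u/(u+4))`,
#'   `b4 = cos(4u^2) + 2`;
#' * `sim4`: `b1 = 2 + cos(pi(6u-5)/3)`, `b2 = (4-4u) exp(3u^2/(3u^2+1))`,
#'   `b3 = u + 2`.
#'
#' @param design design identifier (`"sim1"`..`"sim4"`).
#' @param u covariate vector in `[0, 1]`; required for `sim3`/`sim4`.
#' @return A numeric vector (`sim1`: length 4; `sim2`: length 3) or a
#'   matrix (`sim3`: `n x 4`; `sim4`: `n x 3`).
#' @examples
#' coefficient_values("sim1")
#' coefficient_values("sim3", u = c(0, 0.5, 1))
#' @export
coefficient_values <- function(design, u = NULL) {
  design <- match.arg(design, c("sim1", "sim2", "sim3", "sim4"))
  if (design_has_u(design) && is.null(u))
    stop("design ", design, " has functional coefficients and requires u")
  switch(design,
    sim1 = c(0.5, 0.8, 1, 2),
    sim2 = c(2, 3, 4),
    sim3 = cbind(b1 = 2 + (u + 1)^3,
                 b2 = (2 * u^2 + 3) / 2,
                 b3 = exp(4 * u / (u + 4)),
                 b4 = cos(4 * u^2) + 2),
    sim4 = cbind(b1 = 2 + cos(pi * (6 * u - 5) / 3),
                 b2 = (4 - 4 * u) * exp(3 * u^2 / (3 * u^2 + 1)),
                 b3 = u + 2))
}

#' Generate the response of one replicate
#'
#' Designs `sim1`/`sim3` use the linear-plus-interaction form
#' `y = b1 x1 + b2 x2 + b3 x3 + b4 x4 x5 + e`; designs `sim2`/`sim4` use
#' the nonlinear form `y = b1 x1^2 + b2 x2 x3 + b3 x4 x5 + e`, with
#' coefficients from [coefficient_values()] and `e ~ N(0, 1)` white noise.
#'
#' @param X feature matrix with at least 5 columns.
#' @param design design identifier.
#' @param u covariate for the functional-coefficient designs.
#' @param noise_seed optional seed for the noise draw.
#' @param epsilon optional explicit noise vector (overrides the draw);
#'   mainly for deterministic checks.
#' @return Numeric response vector of length `nrow(X)`.
#' @export
generate_response <- function(X, design, u = NULL, noise_seed = NULL,
                              epsilon = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 5) stop("X must have at least 5 columns")
  n <- nrow(X)
  B <- coefficient_values(design, u)
  bk <- if (is.matrix(B)) function(k) B[, k] else function(k) B[k]
  if (is.null(epsilon)) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    epsilon <- rnorm(n)
  } else if (length(epsilon) != n) {
    stop("epsilon must have length nrow(X)")
  }
  signal <- if (design %in% c("sim1", "sim3")) {
    bk(1) * X[, 1] + bk(2) * X[, 2] + bk(3) * X[, 3] + bk(4) * X[, 4] * X[, 5]
  } else {
    bk(1) * X[, 1]^2 + bk(2) * X[, 2] * X[, 3] + bk(3) * X[, 4] * X[, 5]
  }
  unname(drop(signal + epsilon))
}

#' Generate one full simulation replicate
#'
#' Composes [generate_features()] and [generate_response()].  The supplied
#' seed spawns two substreams (features, noise), so replicates with
#' distinct seeds are independent yet each is bit-reproducible.
#'
#' @inheritParams generate_features
#' @return An object of class `"sim_replicate"`: list with `X`, `y`, `u`
#'   (or `NULL`), `causal`, `design`, `seed`.
#' @export
generate_replicate <- function(design, seed, chol_factor = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  sub <- sample.int(2147483646L, 2)
  feat <- generate_features(design, sub[1], chol_factor)
  y <- generate_response(feat$X, design$design, feat$u, noise_seed = sub[2])
  structure(list(X = feat$X, y = y, u = feat$u, causal = design$causal,
                 design = design, seed = as.integer(seed)),
            class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("Simulation replicate (", x$design$design, "): n = ", nrow(x$X),
      ", p = ", ncol(x$X), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a set of independent replicates
#'
#' A master seed spawns one sub-seed per replicate, so the set is
#' reproducible as a whole while individual replicates stay independent.
#' The AR(1) Cholesky factor is computed once and shared.
#'
#' @param design a [sim_design()] object.
#' @param n_replicates number of replicates.
#' @param master_seed integer master seed.
#' @return A list of `"sim_replicate"` objects.
#' @export
simulate_replicates <- function(design, n_replicates, master_seed = 1) {
  stopifnot(inherits(design, "sim_design"), n_replicates >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_replicates)
  R <- design_cholesky(design)
  lapply(seeds, function(s) generate_replicate(design, s, R))
}
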