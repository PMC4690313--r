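#' Standardize the columns of a feature matrix
#'
#' Centers each column to mean zero and scales to unit sample variance
#' (denominator `n - 1`).  Constant columns cannot be standardized and
#' raise an error naming the offending column.
#'
#' @param X numeric matrix (samples x features).
#' @return The standardized matrix.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("standardization needs at least 2 rows")
  Xc <- sweep(X, 2, colMeans(X))
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad) > 0)
    stop("constant column cannot be standardized: ",
         colnames(X)[bad[1]] %||% paste0("column ", bad[1]))
  sweep(Xc, 2, s, "/")
}

feature_labels <- function(X) colnames(X) %||% paste0("x", seq_len(ncol(X)))

check_xy <- function(X, y) {
  if (!is.numeric(y)) stop("y must be numeric")
  if (nrow(X) != length(y)) stop("nrow(X) and length(y) differ")
}

#' SIS marginal correlation scores
#'
#' Componentwise correlation learning: the score vector is
#' `w = |t(Xs) %*% y|` with `Xs` the column-standardized feature matrix,
#' so ranking by `w` is equivalent to ranking by the absolute Pearson
#' correlation of each feature with the response.
#'
#' @param X feature matrix.
#' @param y response vector.
#' @return Named numeric vector of non-negative scores, one per feature.
#' @export
sis_scores <- function(X, y) {
  X <- as.matrix(X)
  check_xy(X, y)
  w <- abs(drop(crossprod(standardize_columns(X), y)))
  names(w) <- feature_labels(X)
  w
}

#' Sample distance correlation of two vectors
#'
#' The double-centered V-statistic estimator: for pairwise absolute
#' distance matrices of `a` and `b`, each is centered by subtracting row
#' and column means and adding back the grand mean; squared distance
#' covariance is the average elementwise product of the two centered
#' matrices, and the distance correlation normalizes by the marginal
#' distance variances.  Zero is returned when either marginal distance
#' variance vanishes (a constant vector).  The value lies in `[0, 1]` and
#' is zero iff (in population) the two variables are independent.
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return Distance correlation in `[0, 1]`.
#' @examples
#' distance_correlation(1:4, c(2, 4, 6, 8))  # exactly 1 (linear)
#' @export
distance_correlation <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) stop("a and b must be numeric")
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 observations")
  cpp_dcor(as.numeric(a), as.numeric(b))
}

#' DC-SIS distance correlation scores
#'
#' Scores each feature by its sample distance correlation with the
#' response; model-free, sensitive to both linear and nonlinear
#' association.
#'
#' @inheritParams sis_scores
#' @return Named numeric score vector.
#' @export
dcsis_scores <- function(X, y) {
  X <- as.matrix(X)
  check_xy(X, y)
  if (nrow(X) < 2) stop("need at least 2 observations")
  w <- cpp_dcor_columns(X, as.numeric(y))
  names(w) <- feature_labels(X)
  w
}

# Gaussian kernel weight matrix over the observed covariate values;
# row i holds the normalized weights used to estimate E(. | u = u_i).
cc_kernel_weights <- function(u, h) {
  K <- dnorm(outer(u, u, "-") / h)
  K / rowSums(K)
}

cc_scores_given_weights <- function(X, y, W, var_floor = 1e-12) {
  Ex <- W %*% X
  Ex2 <- W %*% X^2
  Ey <- drop(W %*% y)
  Ey2 <- drop(W %*% y^2)
  Exy <- W %*% (X * y)
  covxy <- Exy - Ex * Ey
  vx <- pmax(Ex2 - Ex^2, var_floor)
  vy <- pmax(Ey2 - Ey^2, var_floor)
  colMeans(covxy^2 / (vx * vy))
}

#' CC-SIS conditional correlation scores
#'
#' Screens by the estimated `E[rho^2(x_j, y | u)]` where
#' `rho(x_j, y | u)` is the correlation of feature and response
#' conditional on a covariate `u`.  The conditional moments `E(x|u)`,
#' `E(y|u)`, `E(xy|u)`, `E(x^2|u)`, `E(y^2|u)` are estimated by Gaussian
#' kernel-weighted local averaging at each observed `u_i`; the squared
#' conditional correlation is assembled from them and averaged over the
#' sample.  Conditional variances are floored at `1e-12` before division
#' to guard kernel-sparse regions of `u`.
#'
#' @inheritParams sis_scores
#' @param u covariate vector, values in `[0, 1]`, length `nrow(X)`.
#' @param bandwidth kernel bandwidth; default is the rule of thumb
#'   `1.06 * sd(u) * n^(-1/5)`.  Must be positive.
#' @return Named numeric score vector (each entry in `[0, 1]` up to the
#'   variance floor).
#' @export
conditional_correlation_scores <- function(X, y, u, bandwidth = NULL) {
  X <- as.matrix(X)
  check_xy(X, y)
  if (is.null(u)) stop("conditional correlation screening requires u")
  if (length(u) != nrow(X)) stop("u must have length nrow(X)")
  if (any(u < 0 | u > 1)) stop("u values must lie in [0, 1]")
  if (is.null(bandwidth)) bandwidth <- 1.06 * sd(u) * length(u)^(-1 / 5)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive (supply one explicitly when sd(u) = 0)")
  W <- cc_kernel_weights(u, bandwidth)
  w <- cc_scores_given_weights(X, y, W)
  names(w) <- feature_labels(X)
  w
}

#' Convert a score vector into a full ranking
#'
#' Sorts scores in decreasing order; ties are broken by ascending feature
#' index so the ranking is deterministic.  Non-finite scores are an error
#' naming the offending feature.
#'
#' @param scores numeric score vector (larger = more important).
#' @param method label stored on the ranking.
#' @param d optional candidate-set size to record.
#' @return An object of class `"feature_ranking"`: list with `order`
#'   (feature indices, rank 1 first), `ranks` (the inverse permutation),
#'   `scores`, `method`, `d_selected`.
#' @examples
#' r <- scores_to_ranking(c(0.1, 0.9, 0.5))
#' r$order  # 2 3 1
#' @export
scores_to_ranking <- function(scores, method = "scores", d = NULL) {
  scores <- drop(scores)
  bad <- which(!is.finite(scores))
  if (length(bad) > 0)
    stop("non-finite score for feature ",
         names(scores)[bad[1]] %||% bad[1])
  p <- length(scores)
  ord <- order(-scores, seq_len(p))
  ranks <- integer(p)
  ranks[ord] <- seq_len(p)
  names(ranks) <- names(scores)
  structure(list(order = ord, ranks = ranks, scores = scores,
                 method = method, d_selected = d),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  p <- length(x$order)
  cat("Feature ranking (", x$method, "), p = ", p, "\n", sep = "")
  k <- min(n, p)
  top <- x$order[seq_len(k)]
  lab <- names(x$scores)[top] %||% paste0("x", top)
  df <- data.frame(rank = seq_len(k), feature = lab,
                   score = unname(x$scores[top]))
  print(df, row.names = FALSE)
  if (p > k) cat("... and", p - k, "more features\n")
  invisible(x)
}

# Shared control flow of the iterative screeners: pick `step_size` top
# features by the per-iteration measure, regress the response on everything
# selected so far, re-screen the remaining features against the residuals.
# Iterations continue until all p features are ordered (the selection order
# is the ranking; within an iteration, order by score).  When the residual
# response is numerically zero -- unavoidable once the selected set spans y
# -- every remaining feature ties at score ~0 and is appended in ascending
# index order.
iterative_ranking <- function(X, y, step_size, score_fun, method, d) {
  p <- ncol(X)
  remaining <- seq_len(p)
  selected <- integer(0)
  sel_scores <- numeric(p)
  r <- y
  warned <- FALSE
  ynorm <- max(1, sqrt(sum(y^2)))
  while (length(remaining) > 0) {
    if (sqrt(sum(r^2)) < 1e-10 * ynorm) {
      sel_scores[remaining] <- 0
      selected <- c(selected, remaining)
      break
    }
    sc <- score_fun(remaining, r)
    k <- min(step_size, length(remaining))
    pick_local <- order(-sc, seq_along(sc))[seq_len(k)]
    sel_scores[remaining[pick_local]] <- sc[pick_local]
    selected <- c(selected, remaining[pick_local])
    remaining <- remaining[-pick_local]
    if (length(remaining) == 0) break
    fit <- lm.fit(cbind(1, X[, selected, drop = FALSE]), y)
    if (fit$rank < length(selected) + 1 && !warned) {
      warning("singular design in the conditioning regression; ",
              "residuals taken from the pivoted least-squares projection")
      warned <- TRUE
    }
    r <- fit$residuals
  }
  ranks <- integer(p)
  ranks[selected] <- seq_len(p)
  names(ranks) <- names(sel_scores) <- feature_labels(X)
  structure(list(order = selected, ranks = ranks, scores = sel_scores,
                 method = method, d_selected = d),
            class = "feature_ranking")
}

resolve_iter_sizes <- function(n, p, d, step_size) {
  d <- d %||% suggested_d(n)[1]
  step_size <- step_size %||% ceiling(d / 3)
  if (step_size < 1 || step_size > d) stop("need 1 <= step_size <= d")
  if (d > p) stop("d cannot exceed the number of features")
  list(d = as.integer(d), step_size = as.integer(step_size))
}

#' ISIS: iterated sure independence screening
#'
#' Iterates SIS conditionally on previously selected features: the first
#' iteration keeps the `step_size` top SIS features; the response is then
#' replaced by the residuals of an ordinary least-squares fit on all
#' features selected so far and SIS is re-applied to the remaining
#' features.  Selection order across iterations defines a full ranking of
#' all `p` features, which lets marginally weak but jointly informative
#' features enter ahead of their marginal rank.
#'
#' @inheritParams sis_scores
#' @param d candidate-set size (defaults to `suggested_d(n)[1]`).
#' @param step_size features selected per iteration (default
#'   `ceiling(d/3)`).
#' @return A `"feature_ranking"`; `scores` holds each feature's score at
#'   the iteration in which it was selected (comparable within, not
#'   across, iterations).
#' @export
isis_ranking <- function(X, y, d = NULL, step_size = NULL) {
  X <- as.matrix(X)
  check_xy(X, y)
  sz <- resolve_iter_sizes(nrow(X), ncol(X), d, step_size)
  Xs <- standardize_columns(X)
  score_fun <- function(idx, r) abs(drop(crossprod(Xs[, idx, drop = FALSE], r)))
  iterative_ranking(X, y, sz$step_size, score_fun, "isis", sz$d)
}

#' ICC-SIS: iterated conditional correlation screening
#'
#' Identical control flow to [isis_ranking()], but each iteration scores
#' the remaining features by the conditional correlation measure of
#' [conditional_correlation_scores()] against the current residuals.
#'
#' @inheritParams conditional_correlation_scores
#' @inheritParams isis_ranking
#' @return A `"feature_ranking"`.
#' @export
iccsis_ranking <- function(X, y, u, d = NULL, step_size = NULL,
                           bandwidth = NULL) {
  X <- as.matrix(X)
  check_xy(X, y)
  if (is.null(u)) stop("ICC-SIS requires the covariate u")
  if (length(u) != nrow(X)) stop("u must have length nrow(X)")
  if (any(u < 0 | u > 1)) stop("u values must lie in [0, 1]")
  if (is.null(bandwidth)) bandwidth <- 1.06 * sd(u) * length(u)^(-1 / 5)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive (supply one explicitly when sd(u) = 0)")
  sz <- resolve_iter_sizes(nrow(X), ncol(X), d, step_size)
  W <- cc_kernel_weights(u, bandwidth)
  score_fun <- function(idx, r)
    cc_scores_given_weights(X[, idx, drop = FALSE], r, W)
  iterative_ranking(X, y, sz$step_size, score_fun, "iccsis", sz$d)
}
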