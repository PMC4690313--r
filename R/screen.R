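#' Screen features of an ultrahigh-dimensional continuous phenotype
#'
#' Central fitting function: ranks every feature by one of six screening
#' measures and returns a classed object with print, summary and plot
#' methods.
#'
#' * `"sis"` -- marginal correlation learning ([sis_scores()]);
#' * `"isis"` -- iterated SIS with residual conditioning ([isis_ranking()]);
#' * `"ccsis"` -- conditional correlation given a covariate `u`
#'   ([conditional_correlation_scores()]);
#' * `"iccsis"` -- its iterated variant ([iccsis_ranking()]);
#' * `"dcsis"` -- distance correlation, model-free ([dcsis_scores()]);
#' * `"rf"` -- out-of-bag permutation importance from a regression random
#'   forest ([rf_ranking()]), which also captures interactive and
#'   nonlinear effects with weak marginal signal.
#'
#' Methods other than `"ccsis"`/`"iccsis"` ignore `u` even when supplied,
#' matching the measures' definitions.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y continuous response, length `nrow(X)`.
#' @param u covariate in `[0, 1]` for the conditional methods.
#' @param method screening measure, see above.
#' @param d candidate-set size to record (defaults to
#'   `suggested_d(n)[1]`).
#' @param step_size per-iteration selection size for the iterative methods.
#' @param bandwidth kernel bandwidth for the conditional methods.
#' @param control [forest_control()] for `method = "rf"`.
#' @param permutation_seed PVIM permutation seed for `method = "rf"`.
#' @return An object of classes `"feature_screening"` and
#'   `"feature_ranking"`: `order` (feature indices, most important first),
#'   `ranks`, `scores`, `method`, `d_selected`.
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(100 * 20), 100, 20)
#' y <- X[, 1] + 2 * X[, 2] + rnorm(100)
#' screen_features(X, y, method = "sis", d = 5)
#' @export
screen_features <- function(X, y, u = NULL,
                            method = c("sis", "isis", "ccsis", "iccsis",
                                       "dcsis", "rf"),
                            d = NULL, step_size = NULL, bandwidth = NULL,
                            control = forest_control(),
                            permutation_seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  check_xy(X, y)
  d <- as.integer(d %||% suggested_d(nrow(X))[1])
  rk <- switch(method,
    sis = scores_to_ranking(sis_scores(X, y), "sis", d),
    dcsis = scores_to_ranking(dcsis_scores(X, y), "dcsis", d),
    ccsis = scores_to_ranking(
      conditional_correlation_scores(X, y, u, bandwidth), "ccsis", d),
    isis = isis_ranking(X, y, d, step_size),
    iccsis = iccsis_ranking(X, y, u, d, step_size, bandwidth),
    rf = rf_ranking(X, y, control, permutation_seed, d))
  rk$n <- nrow(X)
  rk$call <- match.call()
  class(rk) <- c("feature_screening", class(rk))
  rk
}

#' @export
print.feature_screening <- function(x, n = 10, ...) {
  cat("Feature screening by ", toupper(x$method), " (n = ", x$n, ", p = ",
      length(x$order), ")\n", sep = "")
  if (!is.null(x$d_selected))
    cat("  candidate-set size d =", x$d_selected, "\n")
  NextMethod()
}

#' @export
summary.feature_screening <- function(object, causal = NULL, ...) {
  out <- list(method = object$method, p = length(object$order),
              n = object$n, d = object$d_selected)
  if (!is.null(causal)) {
    out$causal_ranks <- stats::setNames(object$ranks[causal],
                                        paste0("x", causal))
    out$minimum_model_size <- minimum_model_size(object, causal)
  }
  structure(out, class = "summary.feature_screening")
}

#' @export
print.summary.feature_screening <- function(x, ...) {
  cat("Screening method:", toupper(x$method), "\n")
  cat("n =", x$n, " p =", x$p, " d =", x$d %||% NA, "\n")
  if (!is.null(x$causal_ranks)) {
    cat("ranks of the causal features:\n")
    print(x$causal_ranks)
    cat("minimum model size M =", x$minimum_model_size, "\n")
  }
  invisible(x)
}

#' Score profile of a screening
#'
#' Plots each feature's score against its index, highlighting the top
#' `d_selected` candidates; a quick visual check of how cleanly the screen
#' separates signal from noise.
#'
#' @param x a `"feature_screening"` object.
#' @param highlight how many top features to mark (default `d_selected`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.feature_screening <- function(x, highlight = NULL, ...) {
  p <- length(x$scores)
  highlight <- highlight %||% x$d_selected %||% min(10, p)
  top <- x$order[seq_len(min(highlight, p))]
  graphics::plot(seq_len(p), x$scores, xlab = "feature index",
                 ylab = paste(toupper(x$method), "score"),
                 col = "grey50", pch = 16, cex = 0.6, ...)
  graphics::points(top, x$scores[top], col = "firebrick", pch = 16, cex = 0.8)
  invisible(x)
}
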