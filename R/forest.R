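#' Control parameters for the screening forest
#'
#' @param ntree number of trees (default 500).
#' @param mtry candidate features drawn without replacement at each node;
#'   default (`NULL`) resolves to `max(1, floor(p/3))` at fit time, the
#'   regression-forest convention.
#' @param min_node minimum node size at which a split is still attempted
#'   (default 5); smaller nodes become leaves.
#' @param seed integer seed controlling bootstrap and feature draws.
#' @return An object of class `"forest_control"`.
#' @export
forest_control <- function(ntree = 500, mtry = NULL, min_node = 5, seed = 1) {
  if (ntree < 1) stop("ntree must be at least 1")
  if (min_node < 2) stop("min_node must be at least 2")
  if (!is.null(mtry) && mtry < 1) stop("mtry must be at least 1")
  structure(list(ntree = as.integer(ntree),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_node = as.integer(min_node),
                 seed = as.integer(seed)),
            class = "forest_control")
}

#' Fit a regression random forest for feature screening
#'
#' Grows `ntree` CART regression trees without pruning.  Each tree sees a
#' bootstrap sample of size `n` drawn with replacement; its complement (the
#' out-of-bag set, about `1/e` of the sample on average) is recorded for
#' importance computation.  At every node, `mtry` candidate features are
#' drawn without replacement and the split minimizing the summed child
#' squared error is taken; candidate thresholds are midpoints between
#' consecutive distinct sorted values.  Leaves predict the training mean.
#' The fit is bit-reproducible given `control$seed`.
#'
#' @param X numeric feature matrix (samples x features), all finite.
#' @param y numeric response, all finite.
#' @param control a [forest_control()] object.
#' @return An object of class `"screen_rf"`: trees (each a node matrix),
#'   the in-bag count matrix, dimensions and control settings.  Use
#'   [pvim()] for importances and `predict()` for forest predictions.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(50 * 4), 50, 4)
#' y <- X[, 1] + rnorm(50, sd = 0.1)
#' fit <- grow_forest(X, y, forest_control(ntree = 50, seed = 2))
#' fit
#' @export
grow_forest <- function(X, y, control = forest_control()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_xy(X, y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite (impute or drop missing values first)")
  if (nrow(X) < control$min_node)
    stop("need at least min_node = ", control$min_node, " observations")
  mtry <- control$mtry %||% max(1L, ncol(X) %/% 3L)
  if (mtry > ncol(X)) stop("mtry cannot exceed the number of features")
  set.seed(control$seed)
  fit <- cpp_grow_forest(X, as.numeric(y), control$ntree, mtry,
                         control$min_node)
  if (fit$n_single_leaf > 0)
    warning(fit$n_single_leaf,
            " tree(s) collapsed to a single leaf (no admissible root split)")
  structure(list(trees = fit$trees, inbag = fit$inbag,
                 n = nrow(X), p = ncol(X), mtry = mtry,
                 feature_names = feature_labels(X),
                 control = control, call = match.call()),
            class = "screen_rf")
}

#' @export
print.screen_rf <- function(x, ...) {
  oob <- mean(colSums(x$inbag == 0)) / x$n
  cat("Screening regression forest\n")
  cat("  n = ", x$n, ", p = ", x$p, ", ntree = ", x$control$ntree,
      ", mtry = ", x$mtry, ", min_node = ", x$control$min_node, "\n", sep = "")
  cat(sprintf("  mean out-of-bag fraction: %.3f\n", oob))
  invisible(x)
}

#' Forest (or per-tree) predictions
#'
#' @param object a fitted `"screen_rf"` forest.
#' @param newdata matrix with the training number of columns.
#' @param trees optional tree subset (indices) to average over; default all.
#' @param ... unused.
#' @return Numeric prediction vector.
#' @export
predict.screen_rf <- function(object, newdata, trees = NULL, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    stop("newdata must have ", object$p, " columns")
  trees <- as.integer(trees %||% seq_len(object$control$ntree))
  if (any(trees < 1 | trees > object$control$ntree)) stop("invalid tree index")
  cpp_forest_predict(object$trees, newdata, trees)
}

#' Out-of-bag predictions of one tree, optionally with one feature permuted
#'
#' Returns tree `tree`'s predictions restricted to its out-of-bag set.
#' When `feature` is given, that feature's values are shuffled among the
#' OOB observations according to `perm` (a permutation of
#' `seq_along(oob)`), which is the elementary operation behind the
#' permutation importance: the identity permutation reproduces the
#' unpermuted predictions exactly.
#'
#' @param model a `"screen_rf"` forest.
#' @param X the feature matrix the model was fitted on.
#' @param tree tree index.
#' @param feature optional feature index to permute.
#' @param perm permutation of the OOB positions (required with `feature`).
#' @return Named numeric vector of predictions; names are the OOB row
#'   indices.  Empty when the tree has no OOB observations.
#' @export
predict_oob <- function(model, X, tree, feature = NULL, perm = NULL) {
  stopifnot(inherits(model, "screen_rf"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$p) stop("X must have ", model$p, " columns")
  if (tree < 1 || tree > model$control$ntree) stop("invalid tree index")
  oob <- which(model$inbag[, tree] == 0)
  if (length(oob) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(feature)) {
    feature <- 0L
    perm <- seq_along(oob)
  } else {
    if (feature < 1 || feature > model$p) stop("invalid feature index")
    perm <- perm %||% seq_along(oob)
    if (!setequal(perm, seq_along(oob)))
      stop("perm must be a permutation of seq_along(oob)")
  }
  preds <- cpp_predict_rows(model$trees[[tree]], X, as.integer(oob),
                            as.integer(feature), as.integer(perm))
  stats::setNames(preds, oob)
}

#' Out-of-bag permutation variable importance (PVIM)
#'
#' For each tree `t` and each feature `j` the tree actually splits on, the
#' feature's values are freshly permuted within the tree's out-of-bag set
#' and the per-tree importance is the increase in OOB squared error,
#' normalized by the OOB size:
#' `PVIM_t(j) = (sum of squared OOB errors after permuting x_j -
#' sum before) / |B_t|`.  A feature whose permutation inflates the error
#' therefore receives a positive importance; features never used by a tree
#' contribute exactly zero for that tree, and negative values are kept
#' (they carry ordering information among noise features).  The reported
#' importance averages over all trees.
#'
#' @param model a `"screen_rf"` forest fitted on `(X, y)`.
#' @param X,y the training data.
#' @param permutation_seed seed for the OOB permutations; defaults to
#'   `control$seed + 1` so fit and importance are jointly reproducible.
#' @param keep_per_tree retain the `ntree x p` matrix of per-tree
#'   contributions.
#' @return An object of class `"pvim"`: `importance` (named length-`p`
#'   vector) and optionally `per_tree`.
#' @export
pvim <- function(model, X, y, permutation_seed = NULL, keep_per_tree = FALSE) {
  stopifnot(inherits(model, "screen_rf"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  check_xy(X, y)
  if (ncol(X) != model$p || nrow(X) != model$n)
    stop("X must be the matrix the model was fitted on (", model$n, " x ",
         model$p, ")")
  set.seed(permutation_seed %||% (model$control$seed + 1L))
  res <- cpp_pvim(model$trees, model$inbag, X, as.numeric(y), keep_per_tree)
  imp <- stats::setNames(res$pvim, model$feature_names)
  structure(list(importance = imp,
                 per_tree = if (keep_per_tree) res$per_tree,
                 ntree = model$control$ntree),
            class = "pvim")
}

#' @export
print.pvim <- function(x, n = 10, ...) {
  cat("Permutation variable importance (", x$ntree, " trees)\n", sep = "")
  top <- sort(x$importance, decreasing = TRUE)
  print(head(top, n))
  invisible(x)
}

#' Node-impurity variable importance
#'
#' The forest's second standard importance measure: for each feature, the
#' total decrease in node sum-of-squares attributed to splits on that
#' feature, summed over all trees.  Unlike the permutation measure it is
#' non-negative by construction and rewards a feature for being *chosen*
#' as a splitter rather than for improving out-of-bag prediction, which
#' makes it markedly more stable for features involved in interactions
#' (a heavily-used feature can never receive a negative value), at the
#' price of a known bias toward features offering many candidate cut
#' points.  The screening measure of [rf_ranking()] remains the
#' permutation importance; this accessor is provided for comparison and
#' for robustness checks.
#'
#' @param model a fitted `"screen_rf"` forest.
#' @return Named non-negative numeric vector of length `p`.
#' @export
impurity_importance <- function(model) {
  stopifnot(inherits(model, "screen_rf"))
  imp <- numeric(model$p)
  for (tr in model$trees) {
    internal <- which(tr[, 1] > 0)
    for (k in internal) {
      l <- tr[k, 3]
      r <- tr[k, 4]
      gain <- tr[l, 6] * tr[l, 5]^2 + tr[r, 6] * tr[r, 5]^2 -
        tr[k, 6] * tr[k, 5]^2
      j <- tr[k, 1]
      imp[j] <- imp[j] + gain
    }
  }
  stats::setNames(pmax(imp, 0), model$feature_names)
}

#' Random-forest screening ranking
#'
#' Fits the forest, computes PVIM and returns the descending-importance
#' ranking (ties broken by ascending feature index).
#'
#' @inheritParams grow_forest
#' @inheritParams pvim
#' @param d optional candidate-set size recorded on the ranking.
#' @return A `"feature_ranking"` with `scores` = PVIM.
#' @export
rf_ranking <- function(X, y, control = forest_control(),
                       permutation_seed = NULL, d = NULL) {
  model <- grow_forest(X, y, control)
  imp <- pvim(model, X, y, permutation_seed)
  scores_to_ranking(imp$importance, "rf", d)
}
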