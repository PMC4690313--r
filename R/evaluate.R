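#' Suggested candidate-set sizes
#'
#' The screening literature's rule for how many candidates to retain:
#' `base = floor(n^(4/5) / log(n^(4/5)))` (natural logarithm) and its
#' first three multiples.  For `n = 200` this gives 16, 32 and 48.
#'
#' @param n sample size, at least 2.
#' @return Integer vector `c(base, 2*base, 3*base)`.
#' @examples
#' suggested_d(200)
#' @export
suggested_d <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 2)
    stop("n must be a single finite value >= 2")
  g <- n^0.8
  base <- max(1L, as.integer(floor(g / log(g))))
  base * c(1L, 2L, 3L)
}

as_rank_vector <- function(ranking) {
  if (inherits(ranking, "feature_ranking") || is.list(ranking)) {
    r <- ranking$ranks
    if (is.null(r)) stop("ranking must contain a 'ranks' component")
    r
  } else if (is.numeric(ranking)) {
    ranking
  } else {
    stop("ranking must be a feature_ranking or a rank vector")
  }
}

#' Minimum model size of one ranking
#'
#' The smallest `k` such that the top-`k` candidates contain every causal
#' feature, i.e. the maximum rank over the causal set.  A value equal to
#' the number of causal features means the screen placed them all on top.
#'
#' @param ranking a `"feature_ranking"` (or a bare rank vector, rank 1 =
#'   most important).
#' @param causal indices of the causal features.
#' @return Integer minimum model size.
#' @export
minimum_model_size <- function(ranking, causal) {
  ranks <- as_rank_vector(ranking)
  causal <- as.integer(causal)
  if (any(causal < 1 | causal > length(ranks)))
    stop("causal indices outside 1..p")
  r <- ranks[causal]
  if (any(is.na(r) | r < 1)) stop("causal feature missing from the ranking")
  as.integer(max(r))
}

#' Screening performance criteria over replicates
#'
#' Aggregates a set of replicate rankings from one method into the
#' standard screening comparison criteria:
#'
#' * `avg_ranks`: `R_j`, the mean rank of each causal feature;
#' * `m_values` and `m_quantiles`: the per-replicate minimum model size
#'   `M = max_j rank_j` and its quantiles (linear interpolation between
#'   order statistics, i.e. [stats::quantile()] type 7);
#' * `powers`: for each candidate size `d`, the per-feature selection
#'   probability `p_j(d) = P(rank_j <= d)` and the overall power
#'   `p_a(d) = P(M <= d)`.
#'
#' @param rankings list of replicate rankings (each a `"feature_ranking"`
#'   or rank vector over the same `p` features).
#' @param causal causal feature indices shared by all replicates.
#' @param d vector of candidate-set sizes, e.g. [suggested_d()].
#' @param probs quantile probabilities for `M` (default 5/25/50/75/95%).
#' @param method optional label.
#' @return An object of class `"criteria_report"`.
#' @export
screening_criteria <- function(rankings, causal, d,
                               probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                               method = NULL) {
  if (length(rankings) == 0) stop("no replicate rankings supplied")
  causal <- as.integer(causal)
  d <- as.integer(d)
  R <- vapply(rankings, function(rk) as.integer(as_rank_vector(rk)[causal]),
              integer(length(causal)))
  R <- matrix(R, nrow = length(causal)) # causal x replicates
  if (any(is.na(R))) stop("causal feature missing from a ranking")
  m_values <- apply(R, 2, max)
  avg_ranks <- rowMeans(R)
  names(avg_ranks) <- paste0("x", causal)
  powers <- data.frame(d = d)
  for (j in seq_along(causal))
    powers[[paste0("p", causal[j])]] <- vapply(d, function(dd) mean(R[j, ] <= dd), 0)
  powers$pa <- vapply(d, function(dd) mean(m_values <= dd), 0)
  structure(list(method = method %||% attr(rankings[[1]], "method") %||%
                   rankings[[1]]$method %||% "unknown",
                 avg_ranks = avg_ranks,
                 m_values = as.integer(m_values),
                 m_quantiles = quantile(m_values, probs, type = 7),
                 powers = powers,
                 causal = causal,
                 d = d,
                 n_replicates = length(rankings)),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat("Screening criteria (", x$method, "), ", x$n_replicates,
      " replicates\n", sep = "")
  cat("  average causal ranks R_j:\n")
  print(round(x$avg_ranks, 2))
  cat("  quantiles of the minimum model size M:\n")
  print(round(x$m_quantiles, 2))
  cat("  selection power within d candidates:\n")
  print(x$powers, row.names = FALSE)
  invisible(x)
}
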