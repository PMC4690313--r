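#' Specification of a simulation benchmark run
#'
#' Bundles the designs, methods, replicate count and data dimensions of a
#' comparison run.  The conditional methods (CC-SIS/ICC-SIS) require a
#' covariate; designs `sim1`/`sim2` do not generate one, so for those
#' cells an independent Uniform(0,1) covariate is drawn per replicate.
#'
#' @param designs subset of `c("sim1","sim2","sim3","sim4")`.
#' @param methods subset of
#'   `c("sis","isis","ccsis","iccsis","dcsis","rf")`.
#' @param n_replicates replicates per design (the headline comparison
#'   uses 100).
#' @param n,p,rho data dimensions and AR(1) parameter of every design.
#' @param d candidate sizes for the power criteria; default
#'   [suggested_d()] of `n`.
#' @param master_seed seed from which all per-replicate seeds are spawned.
#' @param forest [forest_control()] shared by the RF cells (its seed is
#'   re-derived per replicate).
#' @param step_size per-iteration size of the iterative methods.
#' @param verbose log one line per replicate to stderr.
#' @return An object of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(designs = c("sim1", "sim2", "sim3", "sim4"),
                           methods = c("sis", "isis", "ccsis", "iccsis",
                                       "dcsis", "rf"),
                           n_replicates = 100, n = 200, p = 1000, rho = 0.4,
                           d = NULL, master_seed = 1,
                           forest = forest_control(), step_size = NULL,
                           verbose = FALSE) {
  designs <- match.arg(designs, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  structure(list(designs = designs, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 n = as.integer(n), p = as.integer(p), rho = rho,
                 d = as.integer(d %||% suggested_d(n)),
                 master_seed = as.integer(master_seed),
                 forest = forest, step_size = step_size,
                 verbose = isTRUE(verbose)),
            class = "benchmark_spec")
}

# one screening of one replicate, dispatched by method name
run_one_method <- function(method, repdata, u_use, spec, forest_seed) {
  X <- repdata$X
  y <- repdata$y
  switch(method,
    sis = scores_to_ranking(sis_scores(X, y), "sis"),
    dcsis = scores_to_ranking(dcsis_scores(X, y), "dcsis"),
    ccsis = scores_to_ranking(
      conditional_correlation_scores(X, y, u_use), "ccsis"),
    isis = isis_ranking(X, y, d = spec$d[1], step_size = spec$step_size),
    iccsis = iccsis_ranking(X, y, u_use, d = spec$d[1],
                            step_size = spec$step_size),
    rf = {
      ctl <- spec$forest
      ctl$seed <- forest_seed
      rf_ranking(X, y, ctl)
    })
}

#' Run the full screening comparison
#'
#' For every requested design, generates `n_replicates` datasets and feeds
#' the *same* replicate data to every requested method, then aggregates
#' each method's rankings into a [screening_criteria()] report.  Identical
#' `master_seed`s give bit-identical reports, and the replicate stream
#' does not depend on which methods are requested, so methods can be
#' compared across separate runs.
#'
#' @param spec a [benchmark_spec()].
#' @return An object of class `"benchmark_reports"`: a nested list
#'   `reports[[design]][[method]]` of `"criteria_report"`s, with the spec
#'   attached as an attribute.
#' @export
run_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$master_seed)
  # one seed block per design, drawn up-front so the stream is fixed
  seed_block <- function() matrix(sample.int(2147483646L,
                                             3L * spec$n_replicates),
                                  nrow = 3L)
  blocks <- stats::setNames(lapply(spec$designs, function(d) seed_block()),
                            spec$designs)
  needs_u <- any(spec$methods %in% c("ccsis", "iccsis"))
  out <- list()
  for (des in spec$designs) {
    dsg <- sim_design(des, spec$n, spec$p, spec$rho)
    R <- design_cholesky(dsg)
    seeds <- blocks[[des]]
    ranks <- stats::setNames(
      lapply(spec$methods, function(m)
        vector("list", spec$n_replicates)), spec$methods)
    for (r in seq_len(spec$n_replicates)) {
      repdata <- generate_replicate(dsg, seeds[1, r], R)
      u_use <- repdata$u
      if (is.null(u_use) && needs_u) {
        set.seed(seeds[2, r])
        u_use <- runif(dsg$n)
      }
      for (m in spec$methods)
        ranks[[m]][[r]] <- run_one_method(m, repdata, u_use, spec,
                                          seeds[3, r])$ranks
      if (spec$verbose)
        message(des, ": replicate ", r, "/", spec$n_replicates, " done")
    }
    out[[des]] <- stats::setNames(
      lapply(spec$methods, function(m)
        screening_criteria(ranks[[m]], dsg$causal, spec$d, method = m)),
      spec$methods)
  }
  structure(out, class = "benchmark_reports", spec = spec)
}

#' @export
print.benchmark_reports <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Benchmark reports: ", length(x), " design(s) x ",
      length(spec$methods), " method(s), ", spec$n_replicates,
      " replicates each\n", sep = "")
  tabs <- render_tables(x)
  cat("\nAverage causal ranks:\n")
  print(tabs$avg_ranks, row.names = FALSE, digits = 4)
  cat("\nQuantiles of the minimum model size:\n")
  print(tabs$m_quantiles, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Lay the benchmark reports out as comparison tables
#'
#' Produces the three standard table families: average causal-feature
#' ranks (methods x features), minimum-model-size quantiles (methods x
#' probabilities) and selection powers (methods x candidate sizes), one
#' row per (design, method) cell.
#'
#' @param reports a `"benchmark_reports"` object (or nested list
#'   `reports[[design]][[method]]` of criteria reports).
#' @return A list of three data frames: `avg_ranks`, `m_quantiles`,
#'   `powers`.
#' @export
render_tables <- function(reports) {
  rows_rank <- list(); rows_q <- list(); rows_pow <- list()
  for (des in names(reports)) {
    for (m in names(reports[[des]])) {
      rep <- reports[[des]][[m]]
      rows_rank[[length(rows_rank) + 1]] <- data.frame(
        design = des, method = m,
        t(stats::setNames(unname(rep$avg_ranks),
                          paste0("R", rep$causal))),
        check.names = FALSE)
      rows_q[[length(rows_q) + 1]] <- data.frame(
        design = des, method = m,
        t(stats::setNames(unname(rep$m_quantiles),
                          paste0("q", sub("%", "", names(rep$m_quantiles))))),
        check.names = FALSE)
      pw <- rep$powers
      pw$design <- des; pw$method <- m
      rows_pow[[length(rows_pow) + 1]] <-
        pw[, c("design", "method", setdiff(names(pw), c("design", "method")))]
    }
  }
  list(avg_ranks = do.call(rbind, rows_rank),
       m_quantiles = do.call(rbind, rows_q),
       powers = do.call(rbind, rows_pow))
}

#' Write rendered benchmark tables to disk
#'
#' Writes each table family as CSV plus an aligned plain-text rendering.
#'
#' @param tables output of [render_tables()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    csv <- file.path(dir, paste0(nm, ".csv"))
    txt <- file.path(dir, paste0(nm, ".txt"))
    write.csv(tables[[nm]], csv, row.names = FALSE)
    writeLines(utils::capture.output(
      print(tables[[nm]], row.names = FALSE, digits = 4)), txt)
    paths <- c(paths, csv, txt)
  }
  invisible(paths)
}
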