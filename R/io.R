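#' Read a delimited feature (genotype) matrix
#'
#' Samples as rows, one header line of feature identifiers; the delimiter
#' (comma, tab, whitespace) is auto-detected.  The `"raw"` dialect
#' additionally tolerates the PLINK `.raw` leading metadata columns
#' (`FID IID PAT MAT SEX PHENOTYPE`), which are split off.  Missing
#' entries are imputed by their column mean (screening and tree code
#' require complete data) and the imputation count is reported via
#' `message()`.
#'
#' @param path file path.
#' @param dialect `"plain"` (all columns numeric features) or `"raw"`.
#' @return Numeric matrix with feature identifiers as column names.
#' @export
read_feature_matrix <- function(path, dialect = c("plain", "raw")) {
  dialect <- match.arg(dialect)
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty feature matrix: ", path)
  if (dialect == "raw") {
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(df))
    df <- df[, setdiff(names(df), meta), drop = FALSE]
    if (ncol(df) == 0) stop("no genotype columns left after dropping metadata")
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(v) & !is.na(df[[j]]))
      if (length(bad) > 0)
        stop("non-numeric value in column '", names(df)[j], "', row ", bad[1])
      df[[j]] <- v
    }
  }
  X <- as.matrix(df)
  nmiss <- sum(is.na(X))
  if (nmiss > 0) {
    allna <- which(colSums(!is.na(X)) == 0)
    if (length(allna) > 0)
      stop("column '", colnames(X)[allna[1]], "' is entirely missing")
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
    message("imputed ", nmiss, " missing entr",
            if (nmiss == 1) "y" else "ies", " by column means")
  }
  X
}

#' Read a phenotype vector
#'
#' One numeric value per sample, in the same order as the feature matrix
#' rows; a single header line is tolerated.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty phenotype file: ", path)
  df <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty phenotype file: ", path)
  v <- df[[1]]
  if (!is.numeric(v)) {
    parsed <- suppressWarnings(as.numeric(v))
    if (any(is.na(parsed) & !is.na(v)))
      stop("non-numeric phenotype value in row ",
           which(is.na(parsed) & !is.na(v))[1])
    v <- parsed
  }
  v
}

#' Read a feature (SNP) genome map
#'
#' Expects three columns -- feature identifier, chromosome label, position
#' in megabases -- either named (`feature_id`, `chromosome`,
#' `position_mb`) or in that order.
#'
#' @param path file path.
#' @return Data frame with columns `feature_id`, `chromosome`,
#'   `position_mb`.
#' @export
read_genome_map <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  wanted <- c("feature_id", "chromosome", "position_mb")
  if (!all(wanted %in% names(df))) {
    if (ncol(df) < 3) stop("genome map needs 3 columns")
    df <- df[, 1:3]
    names(df) <- wanted
  } else {
    df <- df[, wanted]
  }
  df$feature_id <- as.character(df$feature_id)
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in genome map")
  if (!is.numeric(df$position_mb) || any(df$position_mb < 0, na.rm = TRUE))
    stop("position_mb must be non-negative numeric")
  df
}

# numeric chromosome labels first (in numeric order), others appended
# lexically -- "1" < "2" < ... < "19" < "X" < "Y"
chromosome_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  c(u[!is.na(num)][order(num[!is.na(num)])], sort(u[is.na(num)]))
}

#' Importance table for a Manhattan-style display
#'
#' Joins per-feature importances (PVIM or any screening scores) with a
#' genome map and sorts by chromosome then position, ready for plotting
#' importance against genomic location.  No significance threshold is
#' applied: the display itself is the screening statement.  Features
#' absent from the map are dropped with a warning.
#'
#' @param x a `"pvim"` object, a `"feature_ranking"`/`"feature_screening"`,
#'   or a named numeric score vector.
#' @param genome_map a data frame as returned by [read_genome_map()].
#' @return A data frame of class `"manhattan_table"` with columns
#'   `feature_id`, `chromosome`, `position_mb`, `pvim`, `rank`, sorted by
#'   genomic position.
#' @export
manhattan_table <- function(x, genome_map) {
  if (inherits(x, "pvim")) {
    scores <- x$importance
  } else if (inherits(x, "feature_ranking")) {
    scores <- stats::setNames(x$scores,
                              names(x$scores) %||%
                                paste0("x", seq_along(x$scores)))
  } else if (is.numeric(x) && !is.null(names(x))) {
    scores <- x
  } else {
    stop("x must be a pvim, a feature ranking, or a named score vector")
  }
  if (is.null(names(scores))) stop("scores must carry feature names")
  rank <- integer(length(scores))
  rank[order(-scores, seq_along(scores))] <- seq_along(scores)
  keep <- names(scores) %in% genome_map$feature_id
  if (!any(keep)) stop("no ranked feature appears in the genome map")
  if (any(!keep))
    warning(sum(!keep), " feature(s) absent from the genome map were dropped")
  df <- data.frame(feature_id = names(scores)[keep],
                   pvim = unname(scores[keep]),
                   rank = rank[keep],
                   stringsAsFactors = FALSE)
  df <- merge(df, genome_map, by = "feature_id")
  lev <- chromosome_levels(df$chromosome)
  df <- df[order(match(df$chromosome, lev), df$position_mb, df$feature_id),
           c("feature_id", "chromosome", "position_mb", "pvim", "rank")]
  rownames(df) <- NULL
  class(df) <- c("manhattan_table", "data.frame")
  df
}

#' Plot a Manhattan-style importance table
#'
#' Base-graphics plot of importance against cumulative genomic position,
#' chromosomes in alternating colours.
#'
#' @param x a [manhattan_table()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.manhattan_table <- function(x, ...) {
  lev <- chromosome_levels(x$chromosome)
  offs <- 0
  pos <- numeric(nrow(x))
  centers <- numeric(length(lev))
  for (i in seq_along(lev)) {
    sel <- x$chromosome == lev[i]
    pos[sel] <- offs + x$position_mb[sel]
    span <- max(x$position_mb[sel])
    centers[i] <- offs + span / 2
    offs <- offs + span + 1
  }
  cols <- rep(c("grey25", "steelblue"), length.out = length(lev))
  graphics::plot(pos, x$pvim, pch = 16, cex = 0.6,
                 col = cols[match(x$chromosome, lev)],
                 xaxt = "n", xlab = "chromosome", ylab = "PVIM", ...)
  graphics::axis(1, at = centers, labels = lev, cex.axis = 0.8)
  invisible(x)
}

#' Write / read a ranking as tab-separated text
#'
#' Columns `rank`, `feature_id`, `score`, with a header line; the
#' round-trip reconstructs the ranking exactly.
#'
#' @param ranking a `"feature_ranking"`.
#' @param path file path.
#' @return `write_ranking` invisibly returns `path`; `read_ranking`
#'   returns a `"feature_ranking"`.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "feature_ranking"))
  lab <- names(ranking$scores) %||% paste0("x", seq_along(ranking$scores))
  df <- data.frame(rank = seq_along(ranking$order),
                   feature_id = lab[ranking$order],
                   score = unname(ranking$scores[ranking$order]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param method label for the reconstructed ranking; default taken from
#'   the file name.
#' @export
read_ranking <- function(path, method = "file") {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("rank", "feature_id", "score") %in% names(df)))
    stop("ranking file needs columns rank, feature_id, score")
  df <- df[order(df$rank), ]
  p <- nrow(df)
  # the file does not carry original feature positions, so features are
  # re-indexed in rank order: position k holds the rank-k feature
  structure(list(order = seq_len(p),
                 ranks = stats::setNames(as.integer(df$rank), df$feature_id),
                 scores = stats::setNames(df$score, df$feature_id),
                 method = method, d_selected = NULL),
            class = "feature_ranking")
}

#' Write one simulated replicate as delimited text
#'
#' Writes `X.tsv`, `y.tsv` and (when present) `u.tsv` plus a JSON design
#' manifest into `dir`.
#'
#' @param replicate a `"sim_replicate"`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_replicate <- function(replicate, dir) {
  stopifnot(inherits(replicate, "sim_replicate"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(replicate$X, file.path(dir, "X.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(y = replicate$y), file.path(dir, "y.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(replicate$u))
    utils::write.table(data.frame(u = replicate$u), file.path(dir, "u.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  d <- replicate$design
  jsonlite::write_json(
    list(design = d$design, n = d$n, p = d$p, rho = d$rho,
         causal = d$causal, seed = replicate$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
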