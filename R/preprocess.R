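#' Per-gene z-score normalisation
#'
#' Centers and scales every gene row to mean 0 and sample standard deviation
#' 1 (denominator n-1). Rows with zero variance cannot be scaled (and would
#' make downstream Pearson correlations undefined), so they are dropped with
#' a warning.
#'
#' @param x numeric genes-by-samples matrix (rownames = gene IDs).
#' @return Matrix of the same shape minus any dropped constant rows; row and
#'   column order otherwise preserved.
#' @examples
#' zscore_genes(rbind(g1 = c(1, 2, 3)))   # -1 0 1
#' @export
zscore_genes <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples to z-score")
  s <- row_sds(x)
  zero <- s < .Machine$double.eps^0.5
  if (all(zero)) stop("all gene rows are constant; nothing to normalize")
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance gene row(s): ",
            paste(utils::head(rownames(x)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ...")
    x <- x[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  (x - rowMeans(x)) / s
}

#' Rank genes by variance
#'
#' Variance-based feature ranking, computed on the raw (pre-normalisation)
#' values: z-scoring equalises all row variances to 1, so ranking must come
#' first. Ties are broken by gene ID so the ranking is deterministic.
#'
#' @param x numeric genes-by-samples matrix of raw expression values.
#' @return An object of class `"feature_rank"`: list with `gene` (IDs in
#'   descending-variance order), `variance` (matching values), `k` (cutoff,
#'   `NA` until [select_elbow()] is applied) and `method`.
#' @seealso [select_elbow()], [selected_genes()]
#' @export
rank_by_variance <- function(x) {
  x <- as.matrix(x)
  v <- row_sds(x)^2
  ord <- order(-v, rownames(x))
  structure(list(gene = rownames(x)[ord], variance = unname(v[ord]),
                 k = NA_integer_, method = NA_character_),
            class = "feature_rank")
}

#' Choose a feature cutoff at the variance elbow
#'
#' Finds the elbow of the descending variance-over-rank curve as the point of
#' maximum perpendicular distance from the chord joining the first and last
#' points (Kneedle-style, both axes min-max normalised, no smoothing). Genes
#' up to and including the elbow are retained. An explicit `k` overrides the
#' elbow and is recorded as method `"fixed"`, which is how published feature
#' counts are pinned when reproducing an analysis.
#'
#' @param fs a `"feature_rank"` from [rank_by_variance()].
#' @param k optional integer override for the number of genes kept.
#' @return The `"feature_rank"` with `k` and `method` filled in.
#' @export
select_elbow <- function(fs, k = NULL) {
  stopifnot(inherits(fs, "feature_rank"))
  n <- length(fs$gene)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1 || k > n) stop("k must be in 1..", n)
    fs$k <- k
    fs$method <- "fixed"
    return(fs)
  }
  if (n < 3) stop("need at least 3 genes for elbow detection")
  v <- fs$variance
  if (diff(range(v)) < .Machine$double.eps^0.5) {
    warning("flat variance curve; keeping all genes")
    fs$k <- n
    fs$method <- "elbow"
    return(fs)
  }
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (v - v[n]) / (v[1] - v[n])
  # perpendicular distance from the chord (0,1)-(1,0): |x + y - 1| / sqrt(2)
  d <- abs(xs + ys - 1)
  if (max(d) < 1e-8)
    warning("variance curve is close to linear; elbow is weakly determined")
  fs$k <- which.max(d)
  fs$method <- "elbow"
  fs
}

#' Genes retained by a feature selection
#'
#' @param fs a `"feature_rank"` with a cutoff set.
#' @return Character vector of the top-`k` gene IDs by variance.
#' @export
selected_genes <- function(fs) {
  stopifnot(inherits(fs, "feature_rank"))
  if (is.na(fs$k)) stop("no cutoff set; run select_elbow() first")
  fs$gene[seq_len(fs$k)]
}

#' @export
print.feature_rank <- function(x, ...) {
  cat("Variance ranking of", length(x$gene), "genes")
  if (!is.na(x$k))
    cat("; cutoff k =", x$k, sprintf("(%s)", x$method))
  cat("\n")
  invisible(x)
}

#' @export
plot.feature_rank <- function(x, ...) {
  graphics::plot(seq_along(x$variance), x$variance, type = "l",
                 xlab = "gene rank", ylab = "variance", ...)
  if (!is.na(x$k)) graphics::abline(v = x$k, lty = 2, col = 2)
  invisible(x)
}
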