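#' Two-sided p-value for a Pearson correlation
#'
#' Standard t statistic for a correlation estimated from `n` paired
#' observations: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom, two-sided. `|r| = 1` returns 0 by convention.
#'
#' @param r correlation coefficient(s) in \[-1, 1\] (vectorised).
#' @param n number of paired observations (>= 3).
#' @return p-value(s) in \[0, 1\].
#' @examples
#' correlation_pvalue(0.9, 15)   # ~5e-6
#' @export
correlation_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3 observations")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(r) * sqrt(n - 2) / sqrt(1 - r^2),
                            df = n - 2, lower.tail = FALSE))
  pmin(p, 1)
}

#' Stage-specific significance-filtered correlation network
#'
#' Computes all pairwise Pearson correlations over a gene subset using only
#' the samples of one stage, keeps edges with [correlation_pvalue()]
#' `<= alpha` (no multiple-testing correction; the filter is a fixed raw
#' threshold), and drops genes left without any edge. Edge endpoints are
#' stored in canonical order (`gene_a < gene_b`).
#'
#' @param es an [expression_set()] (or a plain matrix plus `stages`).
#' @param stage stage name to subset samples on.
#' @param genes character vector of gene IDs forming the network universe
#'   (typically the top feature-selected genes); default all rows.
#' @param alpha raw p-value threshold, default 1e-4.
#' @param stages stage factor when `es` is a plain matrix.
#' @return An object of class `"stage_network"`: list with `stage`,
#'   `n_input_genes`, `n_samples`, `edges` (data.frame: `gene_a`, `gene_b`,
#'   `r`, `p`, `sign`) and `nodes` (genes incident to >= 1 edge).
#' @export
stage_network <- function(es, stage, genes = NULL, alpha = 1e-4,
                          stages = NULL) {
  if (inherits(es, "expr_set")) {
    x <- es$values
    stages <- es$stages
  } else {
    x <- as.matrix(es)
    if (is.null(stages)) stop("stages required when es is a plain matrix")
  }
  stages <- as.character(stages)
  sel <- stages == stage
  if (!any(sel)) stop("unknown stage: ", stage)
  if (sum(sel) < 3) stop("stage ", stage, " has fewer than 3 samples")
  genes <- genes %||% rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "))
  xs <- x[genes, sel, drop = FALSE]
  n <- ncol(xs)
  ok <- row_sds(xs) > .Machine$double.eps^0.5
  xs <- xs[ok, , drop = FALSE]
  C <- stats::cor(t(xs))
  iu <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[upper.tri(C)]
  p <- correlation_pvalue(r, n)
  keep <- p <= alpha
  ga <- rownames(xs)[iu[keep, 1]]
  gb <- rownames(xs)[iu[keep, 2]]
  swap <- ga > gb
  edges <- data.frame(gene_a = ifelse(swap, gb, ga),
                      gene_b = ifelse(swap, ga, gb),
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] >= 0, "+", "-"),
                      row.names = NULL)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(stage = stage, n_input_genes = length(genes),
                 n_samples = n, edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat(sprintf("Stage '%s' network: %d node(s), %d edge(s) (%d+/%d-) from %d genes, %d samples\n",
              x$stage, length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-"),
              x$n_input_genes, x$n_samples))
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)

#' Common and stage-unique correlation edges
#'
#' Intersects the edge sets of several stage networks (edge identity is the
#' canonical gene pair; sign and magnitude are ignored) and subtracts the
#' common set from each network. The remainder is the *unique network* of
#' each stage — the interactions specific to that point of disease
#' progression — with newly isolated genes removed. By construction
#' `|unique| = |original| - |common|` for every stage.
#'
#' @param networks list of two or more `"stage_network"` objects over a
#'   shared gene universe.
#' @return List with `common` (data.frame of shared `gene_a`/`gene_b`
#'   pairs) and `unique` (list of `"stage_network"` objects named by
#'   stage).
#' @export
common_and_unique <- function(networks) {
  if (length(networks) < 2) stop("need at least 2 networks")
  keys <- lapply(networks, edge_keys)
  common_keys <- Reduce(intersect, keys)
  first <- networks[[1]]$edges
  common <- first[paste(first$gene_a, first$gene_b) %in% common_keys,
                  c("gene_a", "gene_b"), drop = FALSE]
  rownames(common) <- NULL
  uniq <- lapply(networks, function(net) {
    keep <- !(edge_keys(net) %in% common_keys)
    net$edges <- net$edges[keep, , drop = FALSE]
    rownames(net$edges) <- NULL
    net$nodes <- sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
    net
  })
  names(uniq) <- vapply(networks, `[[`, "", "stage")
  list(common = common, unique = uniq)
}

#' Stage-network comparison table
#'
#' One row per stage with node/edge counts of the original and unique
#' networks and the split into positively and negatively correlated edges,
#' mirroring the standard published layout for cross-stage network
#' comparisons.
#'
#' @param networks list of `"stage_network"` objects.
#' @param cu result of [common_and_unique()] on the same list (computed if
#'   omitted).
#' @return data.frame: `stage`, `nodes`, `edges`, `pos`, `neg`,
#'   `unique_nodes`, `unique_edges`, `unique_pos`, `unique_neg`,
#'   `common_edges`.
#' @export
network_summary <- function(networks, cu = NULL) {
  cu <- cu %||% common_and_unique(networks)
  do.call(rbind, lapply(networks, function(net) {
    u <- cu$unique[[net$stage]]
    data.frame(stage = net$stage,
               nodes = length(net$nodes), edges = nrow(net$edges),
               pos = sum(net$edges$sign == "+"),
               neg = sum(net$edges$sign == "-"),
               unique_nodes = length(u$nodes),
               unique_edges = nrow(u$edges),
               unique_pos = sum(u$edges$sign == "+"),
               unique_neg = sum(u$edges$sign == "-"),
               common_edges = nrow(cu$common),
               row.names = NULL)
  }))
}

#' Export a network in SIF format
#'
#' Simple interaction format (one `gene_a pp gene_b` line per edge),
#' readable by Cytoscape.
#'
#' @param net a `"stage_network"`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_sif <- function(net, file) {
  lines <- sprintf("%s\tpp\t%s", net$edges$gene_a, net$edges$gene_b)
  writeLines(lines, file)
  invisible(file)
}

#' Export a network in GraphML format
#'
#' Builds an igraph graph with edge attributes `r`, `p`, `sign` and `stage`
#' and writes GraphML for import into Cytoscape or other viewers.
#'
#' @inheritParams write_sif
#' @return Invisibly, `file`.
#' @export
write_graphml <- function(net, file) {
  if (nrow(net$edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    ed <- net$edges
    ed$stage <- net$stage
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
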