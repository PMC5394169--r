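#' Staged expression set
#'
#' Bundles a genes-by-samples expression matrix with an ordered stage label
#' per sample. This is the input container for [hopfield_fit()] and the
#' stage-network functions. Stages are ordinal (e.g. normal, early disease,
#' advanced disease); their order matters for majority-label tie-breaking
#' and reporting, so it is carried as factor levels.
#'
#' @param values numeric matrix, genes as rows (rownames = gene/probe IDs),
#'   samples as columns (colnames = sample IDs). No missing values.
#' @param stages stage label per sample: either a vector named by sample ID
#'   or an unnamed vector aligned with `colnames(values)`.
#' @param stage_order character vector giving the progression order of the
#'   stages (first = earliest, e.g. "normal"). Defaults to order of first
#'   appearance.
#' @return An object of class `"expr_set"`: a list with elements `values`
#'   (the matrix) and `stages` (a factor aligned to the columns).
#' @examples
#' x <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' es <- expression_set(x, rep(c("normal", "disease"), each = 5),
#'                      stage_order = c("normal", "disease"))
#' es
#' @export
expression_set <- function(values, stages, stage_order = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample IDs in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values; ",
         "use read_expression(impute = TRUE) or clean the input")

  stages <- unlist(stages, use.names = TRUE)
  if (!is.null(names(stages))) {
    missing <- setdiff(colnames(values), names(stages))
    if (length(missing))
      stop("no stage label for sample(s): ", paste(missing, collapse = ", "))
    stages <- stages[colnames(values)]
  } else if (length(stages) != ncol(values)) {
    stop("stages must be named by sample or match the number of samples")
  }
  stages <- as.character(stages)
  stage_order <- stage_order %||% unique(stages)
  if (!all(stages %in% stage_order))
    stop("stage labels not covered by stage_order: ",
         paste(setdiff(stages, stage_order), collapse = ", "))
  stages <- factor(stages, levels = stage_order)
  names(stages) <- colnames(values)
  if (any(table(stages)[unique(as.character(stages))] < 1))
    stop("every stage must have at least one sample")

  structure(list(values = values, stages = stages), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("Staged expression set:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  print(table(stage = x$stages))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read a staged expression dataset from TSV files
#'
#' The expression file is tab-separated with the gene/probe ID in the first
#' column and one header column per sample; the stage file is two-column TSV
#' (sample ID, stage label), headerless or with a header. Gzipped files are
#' accepted (R's readers decompress transparently).
#'
#' @param expr_file path to the genes-by-samples TSV.
#' @param stage_file path to the sample/stage TSV.
#' @param stage_order ordered character vector of stage names; default is
#'   order of first appearance in the stage file.
#' @param impute if `TRUE`, missing expression values are replaced by the
#'   gene's row mean; if `FALSE` (default) missing values are an error.
#' @return An [expression_set()].
#' @export
read_expression <- function(expr_file, stage_file, stage_order = NULL,
                            impute = FALSE) {
  if (!file.exists(expr_file)) stop("expression file not found: ", expr_file)
  if (!file.exists(stage_file)) stop("stage label file not found: ", stage_file)
  tab <- utils::read.delim(expr_file, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    if (!impute)
      stop("missing values in ", expr_file,
           "; rerun with impute = TRUE for per-gene mean imputation")
    for (i in which(rowSums(is.na(values)) > 0)) {
      v <- values[i, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      values[i, ] <- v
    }
  }
  lab <- utils::read.delim(stage_file, header = FALSE,
                           stringsAsFactors = FALSE)
  # tolerate a header row
  if (identical(tolower(lab[1, 1]), "sample") ||
      identical(tolower(lab[1, 1]), "sample_id"))
    lab <- lab[-1, , drop = FALSE]
  stages <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  expression_set(values, stages, stage_order)
}

#' Write a staged expression dataset to TSV files
#'
#' Emits the same two-file format [read_expression()] consumes.
#'
#' @param es an [expression_set()].
#' @param expr_file,stage_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(es, expr_file, stage_file) {
  tab <- data.frame(gene_id = rownames(es$values), es$values,
                    check.names = FALSE)
  utils::write.table(tab, expr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample = colnames(es$values),
                    stage = as.character(es$stages))
  utils::write.table(lab, stage_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(expr_file, stage_file))
}
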