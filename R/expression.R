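#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric gene x sample matrix carrying a
#' processing-stage tag. Stages: \code{"raw"} (non-negative counts),
#' \code{"log2"} (log2(x+1) transformed) and \code{"quantile_normalized"}.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique, non-empty names.
#' @param stage one of \code{"raw"}, \code{"log2"}, \code{"quantile_normalized"}.
#' @return an object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, stage = c("raw", "log2", "quantile_normalized")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (stage == "raw" && any(values < 0))
    stop("raw counts must be non-negative")
  structure(values, stage = stage, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [stage: %s]\n",
              nrow(x), ncol(x), expr_stage(x)))
  invisible(x)
}

#' Processing stage of an expression matrix
#' @param m an \code{expr_matrix}.
#' @return the stage tag, a character scalar.
#' @export
expr_stage <- function(m) attr(m, "stage")

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. All cells must be numeric; the matrix is returned in the
#' \code{"raw"} stage.
#'
#' @param path path to a tab-separated file.
#' @return an \code{expr_matrix} in raw stage.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs gene ids plus at least one sample")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 genes[bad[1]], colnames(vals)[bad[2]], vals[bad[1], bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  expr_matrix(num, stage = "raw")
}

#' Write an expression matrix to TSV
#' @param m an \code{expr_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes with zero reads in every sample
#'
#' Silent genes carry no correlation information and are dropped before
#' normalization; the remaining gene order is preserved.
#'
#' @param m an \code{expr_matrix} in raw stage.
#' @return an \code{expr_matrix} with only genes detected in at least one sample.
#' @export
drop_silent_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_stage(m) != "raw") stop("drop_silent_genes expects a raw-stage matrix")
  keep <- rowSums(m > 0) > 0
  if (!any(keep)) stop("all genes have zero reads in every sample")
  expr_matrix(unclass(m)[keep, , drop = FALSE], stage = "raw")
}

#' Quantile-normalize a numeric matrix across columns
#'
#' Forces every column to share the empirical distribution of column-sorted
#' means. Ties within a column receive the mean of the reference values at
#' their rank positions (mean-of-ranks dialect).
#'
#' @param x numeric matrix (observations x samples).
#' @return matrix of the same shape; every column's sorted values are identical
#'   up to tie collapsing.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Log2-transform and quantile-normalize raw counts
#'
#' Applies \code{log2(x + 1)} per cell, then quantile normalization across
#' samples, yielding the \code{"quantile_normalized"} stage used by
#' \code{\link{coexpression}}.
#'
#' @param m an \code{expr_matrix} in raw stage with >= 2 samples.
#' @return an \code{expr_matrix} in \code{"quantile_normalized"} stage.
#' @export
normalize_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_stage(m) != "raw") stop("normalize_expression expects a raw-stage matrix")
  if (ncol(m) < 2) stop("quantile normalization undefined for a single sample")
  lg <- log2(unclass(m) + 1)
  expr_matrix(quantile_normalize(lg), stage = "quantile_normalized")
}
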