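#' Read a relative concentration index (RCI) table
#'
#' Cytoplasm/nucleus RCI values on the log scale: positive = cytoplasmic,
#' negative = nuclear. The TSV has a header row of cell-line names and a
#' first column of gene ids; blank or \code{NA} cells mark genes not measured
#' in that cell line and are preserved as missing (missing is not zero).
#'
#' @param path path to the TSV.
#' @return an \code{rci_table}: numeric gene x cell-line matrix with NAs for
#'   missing entries.
#' @export
read_rci <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("RCI TSV needs gene ids plus at least one cell line")
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene id in RCI table")
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate cell-line name in RCI table")
  raw <- as.matrix(df[, -1, drop = FALSE])
  blank <- !nzchar(trimws(raw)) | toupper(trimws(raw)) == "NA"
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- is.na(num) & !blank
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric RCI cell at gene '%s', cell line '%s': '%s'",
                 genes[w[1]], colnames(raw)[w[2]], raw[w[1], w[2]]))
  }
  num[blank] <- NA_real_
  if (any(!is.finite(num[!is.na(num)]))) stop("RCI values must be finite")
  dimnames(num) <- list(genes, colnames(raw))
  structure(num, class = c("rci_table", "matrix", "array"))
}

#' Write an RCI table to TSV (missing entries as blanks)
#' @param rci an \code{rci_table} (or numeric matrix with dimnames).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_rci <- function(rci, path) {
  chr <- matrix(ifelse(is.na(rci), "", format(unclass(rci), trim = TRUE, digits = 15)),
                nrow = nrow(rci), dimnames = dimnames(rci))
  df <- data.frame(gene = rownames(chr), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.rci_table <- function(x, ...) {
  cat(sprintf("rci_table: %d genes x %d cell lines, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}
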