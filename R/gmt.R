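#' Read a GMT gene-set library
#'
#' GMT is one gene set per line: term label, description, then gene symbols,
#' all tab-separated. Blank gene fields are dropped; symbols are preserved
#' case-sensitively. Duplicate genes within one set are collapsed (first
#' occurrence kept, so member order is stable for ranked sets).
#'
#' @param path path to a .gmt file.
#' @return a \code{gene_set_library}: a named list of character vectors with a
#'   \code{descriptions} attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 tab-separated fields",
                 which(nf < 3)[1], path))
  terms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(terms))
    stop("duplicate term label in ", path, ": ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    unique(g[nzchar(g)])
  })
  if (any(lengths(sets) == 0))
    stop("GMT term with no genes: ", terms[which(lengths(sets) == 0)[1]])
  names(sets) <- terms
  names(descs) <- terms
  gene_set_library(sets, descriptions = descs)
}

#' Construct a gene-set library
#' @param sets named list of character vectors (term label -> gene symbols).
#' @param descriptions optional named character vector of term descriptions.
#' @return a \code{gene_set_library}.
#' @export
gene_set_library <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("library needs at least one named term")
  if (anyDuplicated(names(sets))) stop("duplicate term labels")
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    descriptions[is.na(descriptions)] <- ""
    names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, class = c("gene_set_library", "list"))
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d terms, set sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a gene-set library to GMT
#'
#' Member order within each line is preserved exactly as given, so ranked
#' (ordered) sets survive a round trip.
#'
#' @param library a \code{gene_set_library} or named list of character vectors.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(library, path) {
  if (!length(library)) stop("refusing to write an empty library")
  descs <- attr(library, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(rep("", length(library)), names(library))
  lines <- vapply(names(library), function(term) {
    paste(c(term, descs[[term]], library[[term]]), collapse = "\t")
  }, "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
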