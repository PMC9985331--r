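#' Label samples by tissue or cell line via text search
#'
#' Free-text sample descriptions are searched for vocabulary terms in three
#' precedence tiers: cell types (mapped to their tissue), then tissue names,
#' then cell-line names. All text and vocabularies are normalized (lowercase,
#' symbols stripped, whitespace squeezed). Cell-line names of three or fewer
#' characters are searched as \code{"<name> cell"} to limit false positives;
#' vocabulary terms shorter than five characters are matched at word
#' boundaries. A sample matching several terms within the winning tier is
#' left unlabeled and flagged ambiguous for manual resolution.
#'
#' @param descriptions named character vector: sample id -> free text.
#' @param cell_type_to_tissue named character vector: cell type -> tissue.
#' @param tissue_names character vector of tissue names.
#' @param cell_lines character vector of cell-line names.
#' @return data.frame with columns \code{sample_id}, \code{kind}
#'   (\code{tissue}/\code{cell_line}/\code{unlabeled}), \code{label},
#'   \code{provenance} (\code{matched_cell_type}, \code{matched_tissue},
#'   \code{matched_cell_line}, \code{ambiguous} or \code{none}).
#' @export
label_samples <- function(descriptions, cell_type_to_tissue = character(0),
                          tissue_names = character(0), cell_lines = character(0)) {
  if (!length(cell_type_to_tissue) && !length(tissue_names) && !length(cell_lines))
    stop("all vocabularies empty")
  if (is.null(names(descriptions))) stop("descriptions must be named by sample id")
  norm <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9 ]", " ", x)
    gsub(" +", " ", trimws(x))
  }
  txt <- norm(descriptions)
  term_regex <- function(term) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
    if (nchar(term) < 5) paste0("\\b", esc, "\\b") else esc
  }
  match_tier <- function(text, terms) {
    hits <- which(vapply(terms, function(t) grepl(term_regex(t), text), TRUE))
    terms[hits]
  }
  ct_terms <- norm(names(cell_type_to_tissue))
  ct_tissue <- unname(cell_type_to_tissue)
  ti_terms <- norm(tissue_names)
  cl_terms <- norm(cell_lines)
  cl_search <- ifelse(nchar(cl_terms) <= 3, paste(cl_terms, "cell"), cl_terms)
  one <- function(sid, text) {
    mk <- function(kind, label, prov)
      data.frame(sample_id = sid, kind = kind, label = label,
                 provenance = prov, stringsAsFactors = FALSE)
    if (length(ct_terms)) {
      h <- match_tier(text, ct_terms)
      if (length(h) >= 1) {
        tiss <- unique(ct_tissue[match(h, ct_terms)])
        if (length(tiss) == 1) return(mk("tissue", tiss, "matched_cell_type"))
        return(mk("unlabeled", NA_character_, "ambiguous"))
      }
    }
    if (length(ti_terms)) {
      h <- match_tier(text, ti_terms)
      if (length(h) == 1) return(mk("tissue", h, "matched_tissue"))
      if (length(h) > 1) return(mk("unlabeled", NA_character_, "ambiguous"))
    }
    if (length(cl_terms)) {
      h <- which(vapply(cl_search, function(t) grepl(term_regex(t), text), TRUE))
      if (length(h) == 1) return(mk("cell_line", cl_terms[h], "matched_cell_line"))
      if (length(h) > 1) return(mk("unlabeled", NA_character_, "ambiguous"))
    }
    mk("unlabeled", NA_character_, "none")
  }
  out <- do.call(rbind, Map(one, names(descriptions), txt))
  rownames(out) <- NULL
  out
}

#' Per-group expression statistics (box-plot summaries)
#'
#' Five-number summary plus sample count of normalized expression for each
#' gene within each labeled sample group. Groups smaller than
#' \code{min_samples} are dropped before statistics are computed.
#'
#' @param m a quantile-normalized \code{expr_matrix}.
#' @param labels data.frame from \code{\link{label_samples}} (or with columns
#'   \code{sample_id}, \code{label}); unlabeled samples are ignored.
#' @param min_samples minimum group size; default 20.
#' @return data.frame with columns \code{gene}, \code{group}, \code{count},
#'   \code{min}, \code{q1}, \code{median}, \code{q3}, \code{max}.
#' @export
group_stats <- function(m, labels, min_samples = 20) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_stage(m) != "quantile_normalized")
    stop("group_stats expects a quantile-normalized matrix")
  lab <- labels[!is.na(labels$label) & labels$sample_id %in% colnames(m), , drop = FALSE]
  groups <- split(lab$sample_id, lab$label)
  groups <- groups[lengths(groups) >= min_samples]
  if (!length(groups)) stop("no group meets the minimum sample count")
  rows <- lapply(names(groups), function(g) {
    sub <- unclass(m)[, groups[[g]], drop = FALSE]
    q <- t(apply(sub, 1, stats::quantile, probs = c(0, .25, .5, .75, 1),
                 names = FALSE, type = 7))
    data.frame(gene = rownames(sub), group = g, count = ncol(sub),
               min = q[, 1], q1 = q[, 2], median = q[, 3], q3 = q[, 4],
               max = q[, 5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
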