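#' Benchmark gene prioritization against knockdown DEGs
#'
#' Tests whether the top correlates of a gene overlap the differentially
#' expressed genes observed after perturbing it: the top \code{top_n} most
#' positively and most negatively correlated genes are intersected with the
#' up- and down-regulated DEG sets (\code{\link{deg_filter}} thresholds), and
#' each of the four overlaps is scored with a right-tailed Fisher exact test
#' over the universe of genes present in both the fit and the DE table.
#'
#' @param c a \code{coexpression} fit.
#' @param gene the perturbed gene.
#' @param de_records data.frame with columns \code{gene}, \code{log2FC},
#'   \code{FDR}, \code{zscore}.
#' @param top_n correlate/DEG list length; default 200.
#' @return data.frame with one row per (correlate direction, DEG direction):
#'   \code{correlates}, \code{degs}, \code{overlap}, \code{fisher_p},
#'   \code{neg_log10_p}.
#' @export
benchmark_overlap <- function(c, gene, de_records, top_n = 200) {
  stopifnot(inherits(c, "coexpression"))
  universe <- intersect(c$gene_ids, de_records$gene)
  universe <- setdiff(universe, gene)
  if (!length(universe)) stop("fit and DE table share no genes")
  degs <- deg_filter(de_records, top_n = top_n)
  tc <- function(dir) suppressWarnings(
    top_correlates(c, gene, top_n, dir, restrict = universe)$gene)
  cors <- list(positive = tc("positive"), negative = tc("negative"))
  rows <- list()
  for (cd in names(cors)) for (dd in c("up", "down")) {
    ov <- overlap_significance(intersect(cors[[cd]], universe),
                               intersect(degs[[dd]], universe), universe)
    rows[[paste(cd, dd)]] <- data.frame(
      correlates = cd, degs = dd, overlap = ov$overlap,
      fisher_p = ov$fisher_p, neg_log10_p = ov$neg_log10_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benchmark candidate ranking against known associations
#'
#' For every term of a gene-set library (e.g. a disease signature), the
#' candidate genes are ranked by their mean PCC with the term's genes, and
#' the ranking is scored by AUROC using the known associated candidates as
#' positives.
#'
#' @param c a \code{coexpression} fit.
#' @param lib a \code{gene_set_library} of term gene sets.
#' @param candidates character vector of candidate genes (e.g. all lncRNAs).
#' @param associations named list / \code{gene_set_library}: term -> known
#'   positive candidates. Terms without at least one positive and one
#'   negative candidate are skipped.
#' @return data.frame: \code{term}, \code{auroc}, \code{n_pos}, \code{n_neg}.
#' @export
benchmark_disease <- function(c, lib, candidates, associations) {
  stopifnot(inherits(c, "coexpression"))
  candidates <- intersect(candidates, c$gene_ids)
  rows <- lapply(names(lib), function(term) {
    pos <- intersect(associations[[term]], candidates)
    n_neg <- length(candidates) - length(pos)
    if (!length(pos) || n_neg == 0)
      return(data.frame(term = term, auroc = NA_real_, n_pos = length(pos),
                        n_neg = n_neg, stringsAsFactors = FALSE))
    rk <- rank_genes_for_set(c, candidates, lib[[term]])
    data.frame(term = term,
               auroc = auroc(rk$mean_pcc, rk$gene %in% pos),
               n_pos = length(pos), n_neg = n_neg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
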