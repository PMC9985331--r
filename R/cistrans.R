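#' Classify a gene's top correlates as cis or trans
#'
#' A correlated partner on the same chromosome as the query is cis; on a
#' different chromosome, trans. Partners are the top \code{k} positive
#' correlates, optionally restricted to a gene class; partners without a
#' chromosome annotation are dropped from both numerator and denominator.
#'
#' @param c a \code{coexpression} fit.
#' @param ann a \code{gene_annotation} (columns \code{gene_id},
#'   \code{chromosome}, \code{is_lncRNA}).
#' @param gene query gene id; must have a chromosome in \code{ann}.
#' @param k number of top correlates; default 100.
#' @param partner_class \code{"all"}, \code{"coding"} or \code{"lncRNA"}.
#' @return list with \code{cis_pct}, \code{trans_pct}, \code{n_used}.
#' @export
assign_modes <- function(c, ann, gene, k = 100,
                         partner_class = c("all", "coding", "lncRNA")) {
  partner_class <- match.arg(partner_class)
  chrom <- ann$chromosome[match(gene, ann$gene_id)]
  if (is.na(chrom) || !nzchar(chrom)) stop("gene lacks a chromosome annotation: ", gene)
  restrict <- switch(partner_class,
                     all = ann$gene_id,
                     coding = ann$gene_id[!ann$is_lncRNA],
                     lncRNA = ann$gene_id[ann$is_lncRNA])
  restrict <- setdiff(restrict[!is.na(ann$chromosome[match(restrict, ann$gene_id)])], gene)
  tc <- suppressWarnings(top_correlates(c, gene, k, "positive", restrict = restrict))
  if (!nrow(tc)) return(list(cis_pct = NA_real_, trans_pct = NA_real_, n_used = 0L))
  partner_chrom <- ann$chromosome[match(tc$gene, ann$gene_id)]
  cis <- 100 * mean(partner_chrom == chrom)
  list(cis_pct = cis, trans_pct = 100 - cis, n_used = nrow(tc))
}

#' Aggregate per-gene cis/trans percentages over a cohort
#'
#' @param c a \code{coexpression} fit.
#' @param ann a \code{gene_annotation}.
#' @param genes cohort of query genes (>= 2 usable).
#' @param k top-correlate count per gene; default 100.
#' @param partner_class as in \code{\link{assign_modes}}.
#' @return list with \code{per_gene} (data.frame gene, cis_pct, trans_pct,
#'   n_used) and \code{summary} (cis/trans mean and sample SD over the cohort).
#' @export
aggregate_modes <- function(c, ann, genes, k = 100,
                            partner_class = c("all", "coding", "lncRNA")) {
  partner_class <- match.arg(partner_class)
  rows <- lapply(genes, function(g) {
    am <- assign_modes(c, ann, g, k, partner_class)
    data.frame(gene = g, cis_pct = am$cis_pct, trans_pct = am$trans_pct,
               n_used = am$n_used, stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  per_gene <- per_gene[per_gene$n_used > 0, , drop = FALSE]
  if (!nrow(per_gene)) stop("empty cohort: no gene had usable correlates")
  summary <- data.frame(
    partner_class = partner_class,
    n_genes = nrow(per_gene),
    cis_mean = mean(per_gene$cis_pct),
    cis_sd = if (nrow(per_gene) > 1) stats::sd(per_gene$cis_pct) else 0,
    trans_mean = mean(per_gene$trans_pct),
    trans_sd = if (nrow(per_gene) > 1) stats::sd(per_gene$trans_pct) else 0,
    stringsAsFactors = FALSE)
  list(per_gene = per_gene, summary = summary)
}
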