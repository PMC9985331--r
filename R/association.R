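#' Mean Pearson correlation between a query gene and a gene set
#'
#' Guilt-by-association summary: the arithmetic mean of r(query, g) over the
#' set members present in the fit. The query itself is excluded from the set
#' if present (its self-correlation of 1 would bias the mean).
#'
#' @param c a \code{coexpression} fit.
#' @param query query gene id.
#' @param genes character vector of set members.
#' @return list with \code{mean_pcc} and \code{n_genes_used}.
#' @export
mean_pcc <- function(c, query, genes) {
  stopifnot(inherits(c, "coexpression"))
  if (!query %in% c$gene_ids) stop("unknown query gene: ", query)
  eff <- setdiff(intersect(genes, c$gene_ids), query)
  if (!length(eff)) stop("empty effective set for query ", query)
  list(mean_pcc = mean(c$r[query, eff]), n_genes_used = length(eff))
}

# mean PCC of EVERY background gene with one term set, vectorized.
# Self-exclusion handled by subtracting each in-set gene's self-correlation.
.mean_pcc_all <- function(c, background, members) {
  eff <- intersect(members, c$gene_ids)
  if (!length(eff)) return(NULL)
  s <- if (length(eff) == 1L) c$r[background, eff] else rowSums(c$r[background, eff, drop = FALSE])
  in_set <- background %in% eff
  n <- rep(length(eff), length(background))
  # a background gene inside the set contributes its own r(g,g); remove it
  s[in_set] <- s[in_set] - diag(c$r)[match(background[in_set], c$gene_ids)]
  n[in_set] <- n[in_set] - 1L
  ok <- n > 0L
  mp <- rep(NA_real_, length(background))
  mp[ok] <- s[ok] / n[ok]
  list(mean_pcc = stats::setNames(mp, background), n_used = stats::setNames(n, background))
}

#' Score a gene-set library against a query gene
#'
#' For every term, the query's mean PCC with the term's genes is compared to
#' the null distribution of that same statistic over all background genes:
#' each term has its own mean and SD (sample SD, denominator n-1), from which
#' a z-score and right-/left-tailed normal p-values are derived. Terms with a
#' degenerate null (SD = 0) are flagged and given p = 0.5 on both tails.
#'
#' @param c a \code{coexpression} fit.
#' @param query query gene id; must be in \code{background}.
#' @param library a \code{gene_set_library} (or named list of gene sets).
#' @param background character vector of query-eligible genes (all must be in
#'   the fit); defaults to every gene in the fit.
#' @return data.frame with one row per term: \code{term}, \code{mean_pcc},
#'   \code{z}, \code{p_right}, \code{p_left}, \code{neg_log10_p_right},
#'   \code{n_genes_used}, \code{degenerate}. Sorted by \code{p_right}.
#' @export
score_library <- function(c, query, library, background = c$gene_ids) {
  stopifnot(inherits(c, "coexpression"))
  if (!query %in% background) stop("query must be part of the background")
  if (!all(background %in% c$gene_ids)) stop("background must be a subset of the fit's genes")
  rows <- lapply(names(library), function(term) {
    all_mp <- .mean_pcc_all(c, background, library[[term]])
    if (is.null(all_mp)) stop("term '", term, "' has no overlap with the fit")
    mp <- all_mp$mean_pcc[query]
    if (is.na(mp)) stop("empty effective set for query ", query, " in term ", term)
    mu <- mean(all_mp$mean_pcc, na.rm = TRUE)
    sigma <- stats::sd(all_mp$mean_pcc, na.rm = TRUE)
    degenerate <- is.na(sigma) || sigma == 0
    z <- if (degenerate) NA_real_ else (mp - mu) / sigma
    p_right <- if (degenerate) 0.5 else stats::pnorm(z, lower.tail = FALSE)
    p_left <- if (degenerate) 0.5 else stats::pnorm(z)
    data.frame(term = term, mean_pcc = unname(mp), z = z,
               p_right = p_right, p_left = p_left,
               neg_log10_p_right = -log10(p_right),
               n_genes_used = unname(all_mp$n_used[query]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_right, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @describeIn coexpression Gene-set association predictions for a query gene:
#'   \code{predict(fit, query, library)} dispatches to
#'   \code{\link{score_library}}.
#' @param object a \code{coexpression} fit.
#' @param query query gene id.
#' @param library a \code{gene_set_library}.
#' @param ... passed to \code{\link{score_library}}.
#' @export
predict.coexpression <- function(object, query, library, ...) {
  score_library(object, query, library, ...)
}

#' Rank candidate genes by mean PCC with a target gene set
#'
#' Used for benchmarks that ask which candidates (e.g. lncRNAs) are most
#' associated with a disease or phenotype gene set.
#'
#' @param c a \code{coexpression} fit.
#' @param candidates character vector of candidate genes.
#' @param target_set character vector, the gene set.
#' @return data.frame (\code{gene}, \code{mean_pcc}, \code{n_genes_used})
#'   sorted by mean PCC descending, ties lexicographic.
#' @export
rank_genes_for_set <- function(c, candidates, target_set) {
  stopifnot(inherits(c, "coexpression"))
  candidates <- intersect(candidates, c$gene_ids)
  if (!length(candidates)) stop("no candidate overlaps the fit")
  all_mp <- .mean_pcc_all(c, candidates, target_set)
  if (is.null(all_mp)) stop("target set has no overlap with the fit")
  out <- data.frame(gene = candidates,
                    mean_pcc = unname(all_mp$mean_pcc),
                    n_genes_used = unname(all_mp$n_used),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$mean_pcc), , drop = FALSE]
  out <- out[order(-out$mean_pcc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a differential-expression table into up/down DEG sets
#'
#' Records must pass all three thresholds: |log2FC| > fc_cut, FDR < fdr_cut
#' and |z| > z_cut. Survivors are split by the sign of log2FC and each side is
#' truncated to the \code{top_n} largest effect sizes (ties: smaller FDR
#' first, then lexicographic gene order).
#'
#' @param records data.frame with columns \code{gene}, \code{log2FC},
#'   \code{FDR}, \code{zscore}.
#' @param top_n per-direction cap; default 200.
#' @param fc_cut,fdr_cut,z_cut thresholds; defaults 0.5, 0.05, 1.645.
#' @return list with character vectors \code{up} and \code{down} (either may
#'   be empty).
#' @export
deg_filter <- function(records, top_n = 200, fc_cut = 0.5, fdr_cut = 0.05,
                       z_cut = 1.645) {
  need <- c("gene", "log2FC", "FDR", "zscore")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (!nrow(records)) stop("empty differential-expression table")
  pass <- abs(records$log2FC) > fc_cut & records$FDR < fdr_cut &
    abs(records$zscore) > z_cut
  kept <- records[pass, , drop = FALSE]
  pick <- function(side) {
    d <- if (side == "up") kept[kept$log2FC > 0, , drop = FALSE]
         else kept[kept$log2FC < 0, , drop = FALSE]
    d <- d[order(-abs(d$log2FC), d$FDR, d$gene), , drop = FALSE]
    utils::head(d$gene, top_n)
  }
  list(up = pick("up"), down = pick("down"))
}

#' Significance of overlap between two gene sets
#'
#' Right-tailed Fisher's exact test for enrichment of the 2x2 table of set
#' membership over a finite universe.
#'
#' @param set_a,set_b character vectors, both subsets of \code{universe}.
#' @param universe character vector of all eligible genes.
#' @return list with \code{overlap}, \code{fisher_p} (right tail) and
#'   \code{neg_log10_p}.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(k,
                  length(set_a) - k,
                  length(set_b) - k,
                  length(universe) - length(set_a) - length(set_b) + k),
                nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(overlap = k, fisher_p = p, neg_log10_p = -log10(p))
}

#' Area under the ROC curve by the Mann-Whitney rank identity
#'
#' AUROC = P(score_pos > score_neg) + 1/2 P(score_pos = score_neg), computed
#' from midranks, equivalent to exhaustive pair counting including ties.
#'
#' @param scores numeric vector of scores (higher = more positive-like),
#'   named or aligned with \code{labels}.
#' @param labels logical vector: TRUE for positives.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' False/true positive rates swept over all score thresholds (descending),
#' for plotting per-cell-line localization ROC curves and similar.
#'
#' @inheritParams auroc
#' @return data.frame with columns \code{fpr}, \code{tpr}, starting at (0,0)
#'   and ending at (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need at least one positive and one negative")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}
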