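#' Prioritize perturbation signatures that modulate query genes
#'
#' Each signature is an up- or down-regulated gene set derived from a
#' perturbation (small molecule or CRISPR knockout) expression profile, with
#' the direction encoded as a \code{_up}/\code{_down} suffix on the term
#' label. For every signature, the query genes are ranked by their mean PCC
#' with the signature's genes and the top \code{top_k} retained. The ranking
#' is then inverted: for each query gene, all signatures that retained it are
#' listed in mean-PCC order. A query matched to an "up" signature is
#' predicted to be upregulated by that perturbation, and vice versa.
#'
#' Right-tailed p-values are computed per signature from the z-score of the
#' query's mean PCC against the mean/SD of all queries' mean PCCs with that
#' signature (the same per-term null as \code{\link{score_library}}).
#'
#' @param c a \code{coexpression} fit.
#' @param signatures a \code{gene_set_library} whose term labels end in
#'   \code{_up} or \code{_down} (case-insensitive; \code{-up}/\code{-down}
#'   and a space separator also accepted).
#' @param queries character vector of query genes (e.g. all lncRNAs).
#' @param top_k per-signature retention cap; default 1000.
#' @return list with
#'   \item{rankings}{data.frame per retained (signature, query): columns
#'     \code{signature}, \code{perturbation}, \code{direction}, \code{query},
#'     \code{rank}, \code{mean_pcc}, \code{p_right}.}
#'   \item{inverted}{a \code{gene_set_library}: one term per query gene whose
#'     ordered members are the signature labels retaining it, by mean PCC
#'     descending.}
#' @export
prioritize_perturbations <- function(c, signatures, queries, top_k = 1000) {
  stopifnot(inherits(c, "coexpression"))
  dir <- parse_signature_direction(names(signatures))
  queries <- intersect(queries, c$gene_ids)
  if (!length(queries)) stop("no query overlaps the fit")
  rows <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    sig <- names(signatures)[i]
    all_mp <- .mean_pcc_all(c, queries, signatures[[sig]])
    if (is.null(all_mp)) next
    mp <- all_mp$mean_pcc
    ok <- !is.na(mp)
    mu <- mean(mp[ok]); sigma <- stats::sd(mp[ok])
    ord <- order(-mp[ok], queries[ok])
    take <- utils::head(ord, top_k)
    q <- queries[ok][take]
    v <- unname(mp[ok][take])
    p <- if (is.na(sigma) || sigma == 0) rep(0.5, length(v))
         else stats::pnorm((v - mu) / sigma, lower.tail = FALSE)
    rows[[i]] <- data.frame(signature = sig,
                            perturbation = dir$base[i],
                            direction = dir$direction[i],
                            query = q,
                            rank = seq_along(q),
                            mean_pcc = v,
                            p_right = p,
                            stringsAsFactors = FALSE)
  }
  rankings <- do.call(rbind, rows)
  if (is.null(rankings) || !nrow(rankings)) stop("no signature overlaps the fit")
  inv_order <- order(rankings$query, -rankings$mean_pcc, rankings$signature)
  inv <- rankings[inv_order, , drop = FALSE]
  inverted <- split(inv$signature, inv$query)
  list(rankings = rankings,
       inverted = gene_set_library(inverted))
}

#' Parse up/down direction suffixes from signature labels
#' @param labels character vector of signature term labels.
#' @return list with \code{base} (label without suffix) and \code{direction}
#'   (\code{"up"} or \code{"down"}); errors on a label without a suffix.
#' @export
parse_signature_direction <- function(labels) {
  has <- grepl("[_ -](up|down)$", labels, ignore.case = TRUE)
  if (any(!has))
    stop("signature label without _up/_down direction suffix: ",
         paste(labels[!has], collapse = ", "))
  direction <- tolower(sub("^.*[_ -](up|down)$", "\\1", labels, ignore.case = TRUE))
  base <- sub("[_ -](up|down)$", "", labels, ignore.case = TRUE)
  list(base = base, direction = direction)
}

#' Table-style report of perturbation predictions for one query gene
#'
#' Rows ordered by right-tailed p-value ascending (the order used in printed
#' top-k tables); mean-PCC ordering is available by sorting the returned
#' frame on \code{mean_pcc}.
#'
#' @param pr result of \code{\link{prioritize_perturbations}}.
#' @param query query gene id.
#' @return data.frame with columns \code{rank}, \code{perturbation},
#'   \code{direction}, \code{mean_pcc}, \code{p_right}.
#' @export
perturbation_report <- function(pr, query) {
  d <- pr$rankings[pr$rankings$query == query, , drop = FALSE]
  if (!nrow(d)) stop("query absent from every signature's retained set: ", query)
  d <- d[order(d$p_right, d$perturbation), , drop = FALSE]
  data.frame(rank = seq_len(nrow(d)),
             perturbation = d$perturbation,
             direction = d$direction,
             mean_pcc = d$mean_pcc,
             p_right = d$p_right,
             stringsAsFactors = FALSE)
}
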