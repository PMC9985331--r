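#' Predict cytoplasm/nucleus localization scores from co-expression ranks
#'
#' Unsupervised guilt-by-association localization: for each query gene, every
#' other gene in the universe (genes shared by the fit and the RCI table,
#' plus the queries) is ranked by its correlation with the query, ranks are
#' scaled to [0, 1] (most correlated -> 1), and the scaled ranks of genes
#' with a measured RCI in a cell line are multiplied by those RCIs and
#' summed. Raw sums are min-max normalized to [0, 1] per cell line across the
#' query set and shifted by -0.5, so reported scores lie in [-0.5, 0.5]:
#' positive = cytoplasmic, negative = nuclear. The query's own RCI never
#' contributes to its sum (self-exclusion), so a measured query cannot leak
#' its label into its own prediction.
#'
#' @param c a \code{coexpression} fit.
#' @param rci an \code{rci_table}.
#' @param queries character vector of query genes, all in the fit.
#' @param cell_lines cell lines to score; default all columns of \code{rci}.
#' @return a \code{localization_scores} object: list with matrices
#'   \code{raw_sum}, \code{score}, \code{n_weights} (queries x cell lines).
#' @export
predict_localization <- function(c, rci, queries, cell_lines = colnames(rci)) {
  stopifnot(inherits(c, "coexpression"))
  if (!all(queries %in% c$gene_ids)) stop("all queries must be in the fit")
  if (!all(cell_lines %in% colnames(rci))) stop("unknown cell line(s)")
  universe <- union(intersect(c$gene_ids, rownames(rci)), queries)
  if (length(universe) < 3) stop("universe too small to rank")
  G <- length(universe)
  w_rci <- matrix(NA_real_, nrow = G, ncol = length(cell_lines),
                  dimnames = list(universe, cell_lines))
  shared <- intersect(universe, rownames(rci))
  w_rci[shared, ] <- unclass(rci)[shared, cell_lines, drop = FALSE]
  if (any(colSums(!is.na(w_rci)) == 0))
    stop("cell line with no measured RCI in the universe: ",
         paste(cell_lines[colSums(!is.na(w_rci)) == 0], collapse = ", "))
  raw <- matrix(NA_real_, length(queries), length(cell_lines),
                dimnames = list(queries, cell_lines))
  nw <- matrix(0L, length(queries), length(cell_lines),
               dimnames = list(queries, cell_lines))
  for (q in queries) {
    idx <- universe != q
    rvec <- c$r[q, universe[idx]]
    # ascending ranks, ties share the mean position; scaled so best -> 1
    rank01 <- (rank(rvec) - 1) / (G - 2)
    for (cl in cell_lines) {
      wv <- w_rci[universe[idx], cl]
      ok <- !is.na(wv)
      raw[q, cl] <- sum(rank01[ok] * wv[ok])
      nw[q, cl] <- sum(ok)
    }
  }
  score <- raw
  if (length(queries) < 2) {
    warning("single query: min-max normalization degenerate, score set to 0")
    score[] <- 0
  } else {
    for (cl in cell_lines) {
      rng <- range(raw[, cl])
      score[, cl] <- if (diff(rng) == 0) 0 else (raw[, cl] - rng[1]) / diff(rng) - 0.5
    }
  }
  structure(list(raw_sum = raw, score = score, n_weights = nw),
            class = "localization_scores")
}

#' @export
print.localization_scores <- function(x, ...) {
  cat(sprintf("localization_scores: %d queries x %d cell lines, score range [%.2f, %.2f]\n",
              nrow(x$score), ncol(x$score), min(x$score), max(x$score)))
  invisible(x)
}

#' Evaluate localization predictions against measured RCIs
#'
#' Per cell line, query genes with a measured RCI beyond the cuts are
#' labeled cytoplasmic (RCI > \code{pos_cut}, positives) or nuclear
#' (RCI < \code{neg_cut}, negatives); genes in between are excluded. The
#' AUROC of the predicted scores is computed by pair counting.
#'
#' @param pred a \code{localization_scores} object.
#' @param rci the \code{rci_table} with measured values.
#' @param pos_cut,neg_cut label cuts; defaults +1 / -1.
#' @return data.frame per cell line: \code{cell_line}, \code{auroc},
#'   \code{n_pos}, \code{n_neg}, \code{skipped} (TRUE when a class is empty),
#'   with the per-cell-line ROC point data.frames in attribute \code{roc}.
#' @export
evaluate_localization <- function(pred, rci, pos_cut = 1, neg_cut = -1) {
  cls <- colnames(pred$score)
  queries <- rownames(pred$score)
  roc <- list()
  rows <- lapply(cls, function(cl) {
    measured <- intersect(queries, rownames(rci))
    v <- unclass(rci)[measured, cl]
    pos <- measured[!is.na(v) & v > pos_cut]
    neg <- measured[!is.na(v) & v < neg_cut]
    if (!length(pos) || !length(neg))
      return(data.frame(cell_line = cl, auroc = NA_real_,
                        n_pos = length(pos), n_neg = length(neg),
                        skipped = TRUE, stringsAsFactors = FALSE))
    s <- pred$score[c(pos, neg), cl]
    l <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
    roc[[cl]] <<- roc_points(s, l)
    data.frame(cell_line = cl, auroc = auroc(s, l),
               n_pos = length(pos), n_neg = length(neg),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "roc") <- roc
  out
}

#' Select the best-performing cell lines for reporting
#'
#' @param evaluations result of \code{\link{evaluate_localization}}.
#' @param k number of cell lines to report; default 5.
#' @return character vector of cell-line names, AUROC descending (ties
#'   lexicographic). If fewer than \code{k} were evaluated, all are returned
#'   with a warning.
#' @export
select_reporting_cell_lines <- function(evaluations, k = 5) {
  ev <- evaluations[!evaluations$skipped, , drop = FALSE]
  ev <- ev[order(-ev$auroc, ev$cell_line), , drop = FALSE]
  if (nrow(ev) < k) {
    warning(sprintf("only %d evaluated cell lines (k = %d); returning all", nrow(ev), k))
    return(ev$cell_line)
  }
  utils::head(ev$cell_line, k)
}
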