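#' Fit a prevalence-filtered gene-gene co-expression matrix
#'
#' The central estimator of the package. Pairwise Pearson correlations are
#' computed between all gene pairs of a quantile-normalized expression matrix,
#' but a pair is only scored when at least one of the two genes is expressed
#' (normalized value > 0) in at least a fraction \code{theta} of the samples;
#' otherwise the correlation is set to exactly 0. This prevalence filter
#' suppresses the misleadingly high correlations that arise between genes
#' detected in only a handful of samples. Genes that are constant across
#' samples have no defined correlation and get r = 0 with all partners.
#'
#' @param m an \code{expr_matrix}. Raw-stage input is normalized first
#'   (\code{\link{normalize_expression}}); quantile-normalized input is used
#'   as is.
#' @param theta prevalence threshold, a fraction in (0, 1]; default 0.3.
#' @return an object of class \code{coexpression}: list with \code{r}
#'   (symmetric gene x gene correlation matrix), \code{gene_ids},
#'   \code{prevalence} (per-gene fraction of samples with value > 0),
#'   \code{theta} and \code{n_samples}.
#' @examples
#' counts <- matrix(rpois(200, 20), 10, 20,
#'                  dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
#' fit <- coexpression(expr_matrix(counts, "raw"), theta = 0.3)
#' print(fit)
#' top_correlates(fit, "g1", k = 3)
#' @export
coexpression <- function(m, theta = 0.3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1)
    stop("theta must be a fraction in (0, 1]")
  if (expr_stage(m) == "raw") {
    m <- normalize_expression(drop_silent_genes(m))
  } else if (expr_stage(m) != "quantile_normalized") {
    stop("coexpression expects a raw or quantile_normalized matrix")
  }
  x <- unclass(m)
  prev <- rowMeans(x > 0)
  sds <- apply(x, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  # constant genes: correlation undefined -> 0 with every partner
  zv <- sds == 0
  r[zv, ] <- 0
  r[, zv] <- 0
  # prevalence rule: pair scored only if max(prev_i, prev_j) >= theta
  pass <- outer(prev, prev, pmax) >= theta
  r[!pass] <- 0
  r[is.na(r)] <- 0
  structure(list(r = r, gene_ids = rownames(x), prevalence = prev,
                 theta = theta, n_samples = ncol(x)),
            class = "coexpression")
}

#' Assemble a coexpression object from a precomputed correlation matrix
#'
#' Used by readers and tests; performs the same validity checks as
#' \code{\link{coexpression}} but takes the correlations as given.
#'
#' @param r symmetric numeric matrix with identical row/column gene names,
#'   entries in [-1, 1].
#' @param theta the prevalence threshold the matrix was built with.
#' @param prevalence optional per-gene prevalence vector.
#' @param n_samples optional sample count.
#' @return a \code{coexpression} object.
#' @export
as_coexpression <- function(r, theta = 0.3, prevalence = NULL, n_samples = NA_integer_) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("r must be a square matrix")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    stop("r must have identical row and column gene names")
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  if (is.null(prevalence)) prevalence <- stats::setNames(rep(1, nrow(r)), rownames(r))
  structure(list(r = r, gene_ids = rownames(r), prevalence = prevalence,
                 theta = theta, n_samples = n_samples),
            class = "coexpression")
}

#' @export
print.coexpression <- function(x, ...) {
  cat(sprintf("coexpression fit: %d genes, %s samples, theta = %g\n",
              length(x$gene_ids),
              ifelse(is.na(x$n_samples), "?", x$n_samples), x$theta))
  cat(sprintf("  genes passing prevalence: %d (%.1f%%)\n",
              sum(x$prevalence >= x$theta), 100 * mean(x$prevalence >= x$theta)))
  invisible(x)
}

#' @export
summary.coexpression <- function(object, ...) {
  off <- object$r[upper.tri(object$r)]
  out <- list(n_genes = length(object$gene_ids),
              n_samples = object$n_samples,
              theta = object$theta,
              n_pass_prevalence = sum(object$prevalence >= object$theta),
              frac_pairs_filtered = mean(off == 0),
              r_quantiles = stats::quantile(off[off != 0],
                                            c(0, .25, .5, .75, 1), na.rm = TRUE))
  class(out) <- "summary.coexpression"
  out
}

#' @export
print.summary.coexpression <- function(x, ...) {
  cat(sprintf("coexpression fit: %d genes, theta = %g\n", x$n_genes, x$theta))
  cat(sprintf("  %d genes pass prevalence; %.1f%% of pairs zeroed/zero\n",
              x$n_pass_prevalence, 100 * x$frac_pairs_filtered))
  cat("  nonzero r quantiles:\n")
  print(round(x$r_quantiles, 3))
  invisible(x)
}

#' Top correlated partners of a gene
#'
#' @param c a \code{coexpression} fit.
#' @param gene query gene id (must be in the fit).
#' @param k number of partners to return.
#' @param direction \code{"positive"} (r descending) or \code{"negative"}
#'   (r ascending).
#' @param restrict optional character vector restricting the candidate
#'   partners (e.g. coding genes only).
#' @return data.frame with columns \code{gene}, \code{r}, ordered by the
#'   requested direction; ties broken lexicographically by gene id. If fewer
#'   than \code{k} candidates exist, all are returned with attribute
#'   \code{truncated = TRUE} and a warning.
#' @export
top_correlates <- function(c, gene, k, direction = c("positive", "negative"),
                           restrict = NULL) {
  stopifnot(inherits(c, "coexpression"))
  direction <- match.arg(direction)
  if (!gene %in% c$gene_ids) stop("unknown gene: ", gene)
  if (k < 1) stop("k must be >= 1")
  cand <- setdiff(c$gene_ids, gene)
  if (!is.null(restrict)) cand <- intersect(cand, restrict)
  rv <- c$r[gene, cand]
  ord <- if (direction == "positive") order(-rv, cand) else order(rv, cand)
  truncated <- length(cand) < k
  if (truncated)
    warning(sprintf("only %d candidates available (k = %d)", length(cand), k))
  take <- ord[seq_len(min(k, length(cand)))]
  out <- data.frame(gene = cand[take], r = unname(rv[take]),
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  out
}

#' Write / read a coexpression fit as TSV
#'
#' Dense symmetric matrix with gene ids in the header and first column;
#' suitable for the moderate gene counts this package targets.
#'
#' @param c a \code{coexpression} fit.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_coexpression <- function(c, path) {
  df <- data.frame(gene = c$gene_ids, as.data.frame(c$r, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(theta = c$theta, n_samples = c$n_samples,
               prevalence = as.list(stats::setNames(c$prevalence, c$gene_ids)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coexpression
#' @export
read_coexpression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  r <- as.matrix(df[, -1, drop = FALSE])
  rownames(r) <- df[[1]]
  theta <- 0.3; prev <- NULL; n <- NA_integer_
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    theta <- meta$theta
    n <- meta$n_samples
    prev <- stats::setNames(unlist(meta$prevalence), names(meta$prevalence))[rownames(r)]
  }
  as_coexpression(r, theta = theta, prevalence = prev, n_samples = n)
}
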