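# Independent oracles, deliberately naive: these re-derive the quantities the
# package computes, by enumeration or two-pass formulas, and must stay free of
# package internals.

# Drop the stage tag / class so plain matrices compare cleanly.
as_plain <- function(m) {
  a <- unclass(m)
  attr(a, "stage") <- NULL
  a
}

# Two-pass Pearson correlation of matrix rows.
naive_pearson <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- x[i, ] - mean(x[i, ]); b <- x[j, ] - mean(x[j, ])
    den <- sqrt(sum(a^2) * sum(b^2))
    out[i, j] <- if (den == 0) 0 else sum(a * b) / den
  }
  out
}

# AUROC by exhaustive pair counting with explicit half-credit for ties.
pairs_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Right-tailed hypergeometric p by direct tail summation over choose().
hyper_tail_p <- function(k, n_a, n_b, universe) {
  i <- k:min(n_a, n_b)
  sum(choose(n_a, i) * choose(universe - n_a, n_b - i)) / choose(universe, n_b)
}

# Build a coexpression fit directly from a hand-specified correlation matrix.
toy_fit <- function(r, theta = 0.3) {
  as_coexpression(r, theta = theta)
}

# Symmetric correlation-like matrix from named pair values; diagonal 1.
corr_from_pairs <- function(genes, pairs) {
  r <- diag(length(genes))
  dimnames(r) <- list(genes, genes)
  for (p in pairs) {
    r[p[[1]], p[[2]]] <- p[[3]]
    r[p[[2]], p[[1]]] <- p[[3]]
  }
  r
}

# Random gene-set library for round-trip property tests.
random_library <- function(n_terms, genes, seed, min_size = 1, max_size = 12) {
  set.seed(seed)
  sets <- lapply(seq_len(n_terms), function(i)
    sample(genes, sample(min_size:max_size, 1)))
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  gene_set_library(sets)
}

write_gtf_lines <- function(path, lines) {
  writeLines(lines, path)
  path
}

gtf_gene_line <- function(chrom, gene_id, gene_name = NULL, gene_type = NULL,
                          start = 100, end = 200) {
  attrs <- sprintf('gene_id "%s";', gene_id)
  if (!is.null(gene_name)) attrs <- paste(attrs, sprintf('gene_name "%s";', gene_name))
  if (!is.null(gene_type)) attrs <- paste(attrs, sprintf('gene_type "%s";', gene_type))
  paste(chrom, "TEST", "gene", start, end, ".", "+", ".", attrs, sep = "\t")
}
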