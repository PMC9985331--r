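#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale bulk RNA-seq corpus with planted
#' co-expression modules: 500 genes x 200 samples, five 20-gene modules whose
#' members share a latent factor giving expected pairwise correlation
#' \code{rho} = 0.9, log-normal-ish counts (latent Gaussian on the log2
#' scale, exponentiated and rounded), 30% of genes flagged lncRNA, genes
#' spread over 10 chromosomes. The first module is designated cytoplasmic and
#' the second nuclear for localization fixtures, with mean |RCI| =
#' \code{rci_effect} = 2 over \code{rci_cell_lines} = 5 cell lines and 10%
#' missing entries.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_modules,module_size planted-module layout
#'   (\code{module_size * n_modules <= n_genes}).
#' @param rho target within-module correlation, in (0, 1).
#' @param noise_sd SD of the latent log2 signal per gene.
#' @param fraction_lncRNA fraction of genes flagged lncRNA.
#' @param n_chromosomes chromosomes to assign genes to.
#' @param rci_cell_lines number of RCI cell lines.
#' @param rci_effect mean |RCI| of planted nuclear/cytoplasmic genes.
#' @param rci_noise_sd SD of RCI noise around the planted mean.
#' @param rci_missingness fraction of RCI entries blanked at random.
#' @param base_log2_expr mean log2 expression level of all genes.
#' @param random_seed integer seed fixing all outputs.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_genes = 500, n_samples = 200, n_modules = 5,
                             module_size = 20, rho = 0.9, noise_sd = 1,
                             fraction_lncRNA = 0.3, n_chromosomes = 10,
                             rci_cell_lines = 5, rci_effect = 2,
                             rci_noise_sd = 0.2, rci_missingness = 0.1,
                             base_log2_expr = 6, random_seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples, n_modules = n_modules,
              module_size = module_size, rho = rho, noise_sd = noise_sd,
              fraction_lncRNA = fraction_lncRNA, n_chromosomes = n_chromosomes,
              rci_cell_lines = rci_cell_lines, rci_effect = rci_effect,
              rci_noise_sd = rci_noise_sd, rci_missingness = rci_missingness,
              base_log2_expr = base_log2_expr, random_seed = as.integer(random_seed))
  if (cfg$n_modules > 0 && cfg$module_size * cfg$n_modules > cfg$n_genes)
    stop("infeasible config: module_size * n_modules exceeds n_genes")
  if (cfg$n_modules > 0 && (rho <= 0 || rho >= 1)) stop("rho must lie in (0, 1)")
  if (cfg$n_samples < 2 || cfg$n_genes < 2) stop("need at least 2 genes and 2 samples")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic counts matrix with planted co-expression modules
#'
#' Module genes share a latent Gaussian factor: on the log2 scale each module
#' gene is \code{sqrt(rho) * factor + sqrt(1 - rho) * noise}, so the expected
#' pairwise within-module correlation is about \code{rho}; background genes
#' are independent noise. Latent values are exponentiated and rounded to
#' non-negative integer counts.
#'
#' @param cfg a \code{synthetic_config}.
#' @return list with \code{counts} (a raw-stage \code{expr_matrix}) and
#'   \code{truth}: data.frame \code{gene_id}, \code{module} (0 = background),
#'   \code{chromosome}, \code{is_lncRNA}, \code{localization}
#'   (\code{cytoplasmic} for module 1 genes, \code{nuclear} for module 2,
#'   else NA).
#' @export
generate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$random_seed)
  G <- cfg$n_genes; S <- cfg$n_samples
  module <- rep(0L, G)
  if (cfg$n_modules > 0)
    module[seq_len(cfg$n_modules * cfg$module_size)] <-
      rep(seq_len(cfg$n_modules), each = cfg$module_size)
  lat <- matrix(stats::rnorm(G * S), G, S)
  if (cfg$n_modules > 0) {
    f <- matrix(stats::rnorm(cfg$n_modules * S), cfg$n_modules, S)
    in_mod <- module > 0
    lat[in_mod, ] <- sqrt(cfg$rho) * f[module[in_mod], , drop = FALSE] +
      sqrt(1 - cfg$rho) * lat[in_mod, , drop = FALSE]
  }
  log2_expr <- cfg$base_log2_expr + cfg$noise_sd * lat
  counts <- round(pmax(2^log2_expr - 1, 0))
  gene_ids <- sprintf("GENE%04d", seq_len(G))
  dimnames(counts) <- list(gene_ids, sprintf("SAMPLE%04d", seq_len(S)))
  loc <- rep(NA_character_, G)
  if (cfg$n_modules >= 1) loc[module == 1L] <- "cytoplasmic"
  if (cfg$n_modules >= 2) loc[module == 2L] <- "nuclear"
  truth <- data.frame(
    gene_id = gene_ids,
    module = module,
    chromosome = paste0("chr", sample.int(cfg$n_chromosomes, G, replace = TRUE)),
    is_lncRNA = stats::runif(G) < cfg$fraction_lncRNA,
    localization = loc,
    stringsAsFactors = FALSE)
  list(counts = expr_matrix(counts, "raw"), truth = truth)
}

#' Gene annotation from synthetic truth
#' @param truth truth data.frame from \code{\link{generate_counts}}.
#' @return a \code{gene_annotation} data.frame.
#' @export
truth_annotation <- function(truth) {
  ann <- data.frame(gene_id = truth$gene_id, symbol = truth$gene_id,
                    chromosome = truth$chromosome, is_lncRNA = truth$is_lncRNA,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Generate a gene-set library aligned with planted modules
#'
#' One term per planted module holding exactly that module's genes (labels
#' \code{"module<k>_planted"}), plus random background terms that never
#' contain a complete module (resampled otherwise).
#'
#' @param truth truth data.frame from \code{\link{generate_counts}}.
#' @param n_background_terms number of random terms; default 20.
#' @param term_size size of each background term; default 20.
#' @param seed integer seed for the background sampling.
#' @return a \code{gene_set_library}.
#' @export
generate_library <- function(truth, n_background_terms = 20, term_size = 20,
                             seed = 1L) {
  if (term_size > nrow(truth)) stop("term_size exceeds gene count")
  set.seed(seed)
  mods <- sort(unique(truth$module[truth$module > 0]))
  sets <- lapply(mods, function(k) truth$gene_id[truth$module == k])
  names(sets) <- sprintf("module%d_planted", mods)
  module_sets <- lapply(sets, sort)
  for (i in seq_len(n_background_terms)) {
    repeat {
      g <- sample(truth$gene_id, term_size)
      contains_module <- any(vapply(module_sets, function(ms) all(ms %in% g), TRUE))
      if (!contains_module) break
    }
    sets[[sprintf("background%03d", i)]] <- g
  }
  gene_set_library(sets)
}

#' Generate an RCI table with planted nuclear/cytoplasmic structure
#'
#' Genes of cytoplasmic modules draw RCIs around \code{+rci_effect}, nuclear
#' around \code{-rci_effect}, all other genes around 0, independently per
#' cell line, with \code{rci_missingness} of entries blanked at random.
#'
#' @param truth truth data.frame (needs both a cytoplasmic and a nuclear
#'   module designated).
#' @param cfg the \code{synthetic_config}.
#' @return an \code{rci_table}.
#' @export
generate_rci <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!any(truth$localization %in% "cytoplasmic") ||
      !any(truth$localization %in% "nuclear"))
    stop("need at least one cytoplasmic and one nuclear designated module")
  set.seed(cfg$random_seed + 1L)
  G <- nrow(truth); C <- cfg$rci_cell_lines
  mu <- ifelse(is.na(truth$localization), 0,
               ifelse(truth$localization == "cytoplasmic", cfg$rci_effect,
                      -cfg$rci_effect))
  vals <- matrix(stats::rnorm(G * C, mean = mu, sd = cfg$rci_noise_sd), G, C)
  vals[matrix(stats::runif(G * C) < cfg$rci_missingness, G, C)] <- NA_real_
  dimnames(vals) <- list(truth$gene_id, sprintf("CELLLINE%02d", seq_len(C)))
  structure(vals, class = c("rci_table", "matrix", "array"))
}

#' Generate a differential-expression table consistent with a planted module
#'
#' Emulates a knockdown of a module gene: fellow module members receive
#' strong negative log2 fold changes with small FDRs, background genes
#' near-zero effects, matching the co-expression structure the counts carry.
#'
#' @param truth truth data.frame.
#' @param module which planted module the perturbed gene belongs to.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{log2FC}, \code{FDR},
#'   \code{zscore}.
#' @export
generate_de_table <- function(truth, module = 1L, seed = 1L) {
  set.seed(seed)
  in_mod <- truth$module == module
  if (!any(in_mod)) stop("no genes in module ", module)
  n <- nrow(truth)
  log2FC <- stats::rnorm(n, mean = ifelse(in_mod, -2, 0), sd = 0.2)
  z <- log2FC / 0.2
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene = truth$gene_id, log2FC = log2FC,
             FDR = stats::p.adjust(p, "BH"), zscore = z,
             stringsAsFactors = FALSE)
}
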