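#' Build a pruned co-expression network around a seed gene
#'
#' The node set is the seed plus its \code{n_top} most positively correlated
#' genes. The network is initialized with each node's
#' \code{init_edges_per_node} highest-weight incident edges (weights are the
#' pairwise correlations among the node set); edges below \code{min_weight}
#' are then dropped, except that the seed's \code{seed_keep} highest-weight
#' edges are protected and always shown. While the average degree is at least
#' \code{target_avg_degree}, each hub (degree > \code{hub_degree}) loses its
#' lowest-weight unprotected edge; when no hub remains, the single globally
#' lowest-weight unprotected edge is removed instead. Ties are broken
#' lexicographically on (weight, sorted gene pair), making the result
#' deterministic.
#'
#' @param c a \code{coexpression} fit.
#' @param seed seed gene id.
#' @param ann optional \code{gene_annotation} supplying node chromosomes.
#' @param n_top number of correlates to include; default 100.
#' @param min_weight minimum unprotected edge weight; default 0.3.
#' @param init_edges_per_node edges per node at initialization; default 3.
#' @param hub_degree degree above which a node is a hub; default 10.
#' @param target_avg_degree pruning stops when average degree drops below
#'   this; default 3.
#' @param seed_keep number of protected seed edges; default 5.
#' @return a \code{coex_network}: list with \code{nodes} (data.frame
#'   \code{id}, \code{chromosome}, \code{is_seed}) and \code{edges}
#'   (data.frame \code{from}, \code{to}, \code{weight}, \code{protected}),
#'   edges stored with \code{from < to} and sorted.
#' @export
build_network <- function(c, seed, ann = NULL, n_top = 100, min_weight = 0.3,
                          init_edges_per_node = 3, hub_degree = 10,
                          target_avg_degree = 3, seed_keep = 5) {
  stopifnot(inherits(c, "coexpression"))
  if (!seed %in% c$gene_ids) stop("unknown seed gene: ", seed)
  if (n_top < 1) stop("n_top must be >= 1")
  others <- setdiff(c$gene_ids, seed)
  rv <- c$r[seed, others]
  pos <- others[rv > 0]
  if (!length(pos)) {
    warning("seed has no positive correlates; returning single-node network")
    return(.new_network(seed, character(0), ann,
                        data.frame(from = character(0), to = character(0),
                                   weight = numeric(0), protected = logical(0))))
  }
  ord <- order(-rv[match(pos, others)], pos)
  nodes <- c(seed, utils::head(pos[ord], n_top))
  w <- c$r[nodes, nodes]

  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  # candidate edges: all ordered pairs among nodes
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ed <- data.frame(from = pmin(nodes[idx[, 1]], nodes[idx[, 2]]),
                   to = pmax(nodes[idx[, 1]], nodes[idx[, 2]]),
                   weight = w[idx], stringsAsFactors = FALSE)
  ed$key <- pair_key(ed$from, ed$to)

  # protected: seed's seed_keep highest-weight incident edges (pre-drop)
  seed_ed <- ed[ed$from == seed | ed$to == seed, , drop = FALSE]
  seed_ed <- seed_ed[order(-seed_ed$weight, seed_ed$from, seed_ed$to), , drop = FALSE]
  protected_keys <- utils::head(seed_ed$key, seed_keep)

  # initialization: union over nodes of each node's top init_edges_per_node edges
  init_keys <- unique(unlist(lapply(nodes, function(nd) {
    inc <- ed[ed$from == nd | ed$to == nd, , drop = FALSE]
    inc <- inc[order(-inc$weight, inc$from, inc$to), , drop = FALSE]
    utils::head(inc$key, init_edges_per_node)
  })))
  keep <- ed[ed$key %in% union(init_keys, protected_keys), , drop = FALSE]
  keep$protected <- keep$key %in% protected_keys
  keep <- keep[keep$protected | keep$weight >= min_weight, , drop = FALSE]

  # iterative hub pruning
  avg_degree <- function(e) 2 * nrow(e) / length(nodes)
  repeat {
    if (nrow(keep) == 0 || avg_degree(keep) < target_avg_degree) break
    if (!any(!keep$protected)) break
    deg <- table(factor(c(keep$from, keep$to), levels = nodes))
    hubs <- sort(names(deg)[deg > hub_degree])
    removed_any <- FALSE
    if (length(hubs)) {
      for (h in hubs) {
        inc <- which((keep$from == h | keep$to == h) & !keep$protected)
        if (!length(inc)) next
        o <- inc[order(keep$weight[inc], keep$from[inc], keep$to[inc])]
        keep <- keep[-o[1], , drop = FALSE]
        removed_any <- TRUE
        if (avg_degree(keep) < target_avg_degree) break
      }
    }
    if (!removed_any) {
      unprot <- which(!keep$protected)
      if (!length(unprot)) break
      o <- unprot[order(keep$weight[unprot], keep$from[unprot], keep$to[unprot])]
      keep <- keep[-o[1], , drop = FALSE]
    }
  }
  keep <- keep[order(keep$from, keep$to), , drop = FALSE]
  .new_network(seed, setdiff(nodes, seed), ann,
               keep[, c("from", "to", "weight", "protected")])
}

.new_network <- function(seed, others, ann, edges) {
  ids <- c(seed, others)
  chrom <- rep(NA_character_, length(ids))
  if (!is.null(ann)) chrom <- ann$chromosome[match(ids, ann$gene_id)]
  nodes <- data.frame(id = ids, chromosome = chrom,
                      is_seed = ids == seed, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("coex_network: %d nodes, %d edges (avg degree %.2f), seed %s\n",
              nrow(x$nodes), nrow(x$edges),
              ifelse(nrow(x$nodes) > 0, 2 * nrow(x$edges) / nrow(x$nodes), 0),
              x$nodes$id[x$nodes$is_seed][1]))
  invisible(x)
}

#' Average node degree of a network
#' @param net a \code{coex_network}.
#' @return 2E/N over all nodes (isolated nodes included).
#' @export
network_avg_degree <- function(net) 2 * nrow(net$edges) / nrow(net$nodes)

#' Write a network as JSON node-link and edge-list TSV
#' @param net a \code{coex_network}.
#' @param json_path,tsv_path output paths; either may be NULL to skip.
#' @return invisibly, NULL.
#' @export
write_network <- function(net, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = net$nodes, links = net$edges),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(net$edges[, c("from", "to", "weight")], tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("source", "target", "weight"))
  }
  invisible(NULL)
}
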