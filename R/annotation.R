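#' Read gene annotation from GTF
#'
#' Extracts one record per gene from a GENCODE-dialect GTF: the stable
#' (version-stripped) gene id, the display symbol (\code{gene_name} when
#' present, otherwise the stable id), the chromosome (GTF field 1), and a
#' long-non-coding flag. A gene is flagged lncRNA when it appears in
#' \code{lncrna_gtf} (a dedicated long-non-coding annotation file, when
#' given) or, otherwise, when its \code{gene_type}/\code{gene_biotype}
#' attribute is \code{"lncRNA"}.
#'
#' @param path path to a GTF file with gene-level (or any) records carrying
#'   \code{gene_id} attributes.
#' @param lncrna_gtf optional path to a second GTF whose gene ids define the
#'   lncRNA set.
#' @param aliases optional path to a two-column TSV (stable id, symbol)
#'   overriding symbols for listed genes.
#' @return a \code{gene_annotation} data.frame with columns \code{gene_id},
#'   \code{symbol}, \code{chromosome}, \code{is_lncRNA}.
#' @export
read_gene_annotation <- function(path, lncrna_gtf = NULL, aliases = NULL) {
  ann <- .gtf_gene_table(path)
  if (!nrow(ann)) stop("no gene records with gene_id found in ", path)
  if (!is.null(lncrna_gtf)) {
    lnc <- .gtf_gene_table(lncrna_gtf)
    ann$is_lncRNA <- ann$gene_id %in% lnc$gene_id
  }
  if (!is.null(aliases)) {
    al <- utils::read.delim(aliases, header = FALSE, sep = "\t",
                            colClasses = "character")
    al[[1]] <- strip_gene_version(al[[1]])
    hit <- match(ann$gene_id, al[[1]])
    ann$symbol[!is.na(hit)] <- al[[2]][hit[!is.na(hit)]]
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Strip the trailing version suffix from Ensembl-style gene ids
#' @param ids character vector of gene ids (e.g. \code{"ENSG00000228630.7"}).
#' @return ids without trailing \code{.N} suffixes; idempotent.
#' @export
strip_gene_version <- function(ids) sub("(\\.[0-9]+)+$", "", ids)

.gtf_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- rtracklayer::readGFF(path,
                            columns = c("seqid", "type"),
                            tags = c("gene_id", "gene_name", "gene_type", "gene_biotype"))
  g <- as.data.frame(g)
  g <- g[!is.na(g$gene_id) & nzchar(g$gene_id), , drop = FALSE]
  if (!nrow(g)) stop("no records with gene_id in ", path)
  gid <- strip_gene_version(g$gene_id)
  chrom <- as.character(g$seqid)
  # one record per stable id; chromosome must be consistent
  first <- !duplicated(gid)
  conflict <- tapply(chrom, gid, function(x) length(unique(x)) > 1)
  if (any(conflict))
    stop("conflicting chromosomes for gene_id: ",
         paste(names(conflict)[conflict], collapse = ", "))
  name <- if ("gene_name" %in% names(g)) as.character(g$gene_name) else rep(NA_character_, nrow(g))
  biotype <- rep(NA_character_, nrow(g))
  if ("gene_type" %in% names(g)) biotype <- as.character(g$gene_type)
  if ("gene_biotype" %in% names(g)) {
    bb <- as.character(g$gene_biotype)
    biotype[is.na(biotype)] <- bb[is.na(biotype)]
  }
  # prefer a record that carries a gene_name for each id
  ord <- order(gid, is.na(name) | !nzchar(ifelse(is.na(name), "", name)))
  gid <- gid[ord]; chrom <- chrom[ord]; name <- name[ord]; biotype <- biotype[ord]
  first <- !duplicated(gid)
  sym <- ifelse(!is.na(name[first]) & nzchar(name[first]), name[first], gid[first])
  data.frame(gene_id = gid[first],
             symbol = sym,
             chromosome = chrom[first],
             is_lncRNA = !is.na(biotype[first]) & biotype[first] == "lncRNA",
             stringsAsFactors = FALSE)
}
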