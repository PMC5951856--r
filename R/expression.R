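## Expression correlation map: log2(1+TPM) transform, high-variance gene
## selection, sample-sample Pearson correlation, hierarchical clustering.

#' Sample-sample correlation map over high-variance genes
#'
#' Values are transformed `log2(1 + TPM)`; zero-variance genes are excluded;
#' genes are ranked by variance of the transformed values (ties broken by
#' gene id) and the chosen gene set retained; pairwise Pearson correlation
#' between samples is computed over those genes and hierarchically clustered
#' (complete linkage on Euclidean distances between correlation-matrix rows).
#'
#' @param mat non-negative TPM matrix, genes x samples, with dimnames.
#' @param top_n number of top-variance genes (default 500); used when
#'   `gene_set = "top_n"`.
#' @param gene_set `"top_n"` (default), `"var_gt_1"` (all genes with
#'   variance > 1), or `"all"` (the full transcriptome) — the two robustness
#'   sets are available on request.
#' @param method,linkage distance and linkage for the clustering
#'   (defaults Euclidean / complete).
#' @return list: `correlation` (samples x samples), `hclust`, `order`
#'   (dendrogram sample order), `genes_used`.
#' @export
correlation_map <- function(mat, top_n = 500L,
                            gene_set = c("top_n", "var_gt_1", "all"),
                            method = "euclidean", linkage = "complete") {
  gene_set <- match.arg(gene_set)
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  if (any(mat < 0)) stop("TPM values must be non-negative")
  lg <- log2(1 + mat)
  v <- apply(lg, 1, stats::var)
  nz <- v > 0
  lg <- lg[nz, , drop = FALSE]
  v <- v[nz]
  genes <- switch(gene_set,
    top_n = {
      if (top_n > nrow(lg)) {
        stop("top_n exceeds available genes after zero-variance removal")
      }
      ord <- order(-v, rownames(lg))
      rownames(lg)[ord[seq_len(top_n)]]
    },
    var_gt_1 = rownames(lg)[v > 1],
    all = rownames(lg)
  )
  sub <- lg[genes, , drop = FALSE]
  cc <- stats::cor(sub, method = "pearson")
  hc <- stats::hclust(stats::dist(cc, method = method), method = linkage)
  list(correlation = cc, hclust = hc, order = colnames(cc)[hc$order],
       genes_used = genes)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. from [correlation_map()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
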