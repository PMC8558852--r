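#' Rebuild the packaged pair-table fixture as a coexpression network
#'
#' Turns the `table3` fixture (lncRNA--mRNA pairs from the
#' cohort-difference network, with published log2 fold changes) into a
#' `coex_network` plus the matching annotation and DE table, using the
#' synthetic coordinate fixture for genomic positions. Useful for
#' exercising [lncrna_mrna_pairs()], [antisense_pairs()] and
#' [component_census()] against known summary counts.
#'
#' @return list with `network`, `annotation`, `de`, `pairs` (the raw
#'   fixture rows).
#' @export
table3_as_network <- function() {
  t3 <- load_fixture("table3")
  coords <- load_fixture("table3_coords_synthetic")
  edges <- data.frame(from = pmin(t3$lncrna_id, t3$mrna_id),
                      to = pmax(t3$lncrna_id, t3$mrna_id),
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edge_key(edges$from, edges$to)), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  ids <- sort(unique(c(t3$lncrna_id, t3$mrna_id)))
  ann <- coords[match(ids, coords$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  nodes <- ann[, c("gene_id", "biotype")]
  de <- rbind(
    data.frame(gene_id = t3$lncrna_id, log2fc = t3$lncrna_log2fc,
               fdr = t3$lncrna_adj_p, stringsAsFactors = FALSE),
    data.frame(gene_id = t3$mrna_id, log2fc = t3$mrna_log2fc,
               fdr = t3$mrna_adj_p, stringsAsFactors = FALSE)
  )
  de <- de[!duplicated(de$gene_id), , drop = FALSE]
  rownames(de) <- NULL
  list(network = coex_network(nodes, edges), annotation = ann, de = de,
       pairs = t3)
}
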