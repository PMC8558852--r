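#' Difference, intersection or symmetric difference of two networks
#'
#' Edge identity is the unordered gene pair; sign/weight metadata is
#' ignored when comparing. The result's nodes are the endpoints of the
#' surviving edges.
#'
#' @param a,b `coex_network` objects over the same gene universe.
#' @param mode `"difference"` (edges of `a` not in `b`), `"intersection"`,
#'   or `"symmetric_difference"`.
#' @export
network_difference <- function(a, b,
                               mode = c("difference", "intersection",
                                        "symmetric_difference")) {
  mode <- match.arg(mode)
  ka <- edge_key(a$edges$from, a$edges$to)
  kb <- edge_key(b$edges$from, b$edges$to)
  edges <- switch(mode,
    difference = a$edges[!(ka %in% kb), , drop = FALSE],
    intersection = a$edges[ka %in% kb, , drop = FALSE],
    symmetric_difference = rbind(
      a$edges[!(ka %in% kb), , drop = FALSE],
      b$edges[!(kb %in% ka), , drop = FALSE]
    )
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$from, edges$to)))
  nodes <- rbind(a$nodes, b$nodes)
  nodes <- nodes[!duplicated(nodes$gene_id), , drop = FALSE]
  nodes <- nodes[match(ids, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  coex_network(nodes, edges)
}

#' Census of connected components by size class
#'
#' Finds connected components and tallies them as pairs (size 2), trios
#' (3), quartets (4), quintets (5), plus a list of the sizes of all
#' components with at least `large_min` nodes; also tallies lncRNA and
#' mRNA counts over all (non-isolated) nodes.
#'
#' @param net a `coex_network`.
#' @param annotation annotation table supplying `biotype`; must cover all
#'   nodes.
#' @param large_min minimum size counted as a "large" subnetwork
#'   (default 6).
#' @return a `component_census` list.
#' @export
component_census <- function(net, annotation, large_min = 6) {
  bt <- annotation$biotype[match(net$nodes$gene_id, annotation$gene_id)]
  if (anyNA(bt)) {
    stop_argument("nodes without biotype: ",
                  paste(head(net$nodes$gene_id[is.na(bt)], 10),
                        collapse = ", "))
  }
  if (nrow(net$nodes) == 0) {
    sizes <- integer()
  } else {
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = net$nodes$gene_id)
    sizes <- as.integer(igraph::components(g)$csize)
  }
  structure(list(
    n_nodes = nrow(net$nodes),
    n_lncrna = sum(bt == "lncRNA"),
    n_mrna = sum(bt == "mRNA"),
    n_components = length(sizes),
    pairs = sum(sizes == 2),
    trios = sum(sizes == 3),
    quartets = sum(sizes == 4),
    quintets = sum(sizes == 5),
    large = sort(sizes[sizes >= large_min], decreasing = TRUE),
    sizes = sort(sizes, decreasing = TRUE)
  ), class = "component_census")
}

#' @export
print.component_census <- function(x, ...) {
  cat(sprintf(paste0("component_census: %d nodes (%d lncRNA, %d mRNA); ",
                     "%d pairs, %d trios, %d quartets, %d quintets"),
              x$n_nodes, x$n_lncrna, x$n_mrna,
              x$pairs, x$trios, x$quartets, x$quintets))
  if (length(x$large)) {
    cat(sprintf(", large: %s", paste(x$large, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Extract lncRNA--mRNA edges as a pair table
#'
#' One row per network edge joining a lncRNA node to an mRNA node,
#' annotated with both genes' log2 fold changes from a DE table. The
#' counts of distinct mRNAs coexpressed with at least one lncRNA, and of
#' those upregulated, are available via [count_coexpressed_mrnas()].
#'
#' @param net a `coex_network`.
#' @param annotation annotation table supplying `biotype` and `symbol`.
#' @param de optional `de_table` supplying `log2fc` per gene.
#' @return a `pair_table` data.frame: `lncrna_id`, `lncrna_symbol`,
#'   `lncrna_log2fc`, `mrna_id`, `mrna_symbol`, `mrna_log2fc`, `antisense`
#'   (NA until [antisense_pairs()] is applied).
#' @export
lncrna_mrna_pairs <- function(net, annotation, de = NULL) {
  bt <- setNames(annotation$biotype, annotation$gene_id)
  sym <- setNames(annotation$symbol, annotation$gene_id)
  lfc <- if (!is.null(de)) setNames(de$log2fc, de$gene_id) else numeric()
  e <- net$edges
  bt_from <- bt[e$from]
  bt_to <- bt[e$to]
  mixed <- (bt_from == "lncRNA" & bt_to == "mRNA") |
    (bt_from == "mRNA" & bt_to == "lncRNA")
  e <- e[which(mixed), , drop = FALSE]
  if (nrow(e) == 0) {
    res <- data.frame(lncrna_id = character(), lncrna_symbol = character(),
                      lncrna_log2fc = numeric(), mrna_id = character(),
                      mrna_symbol = character(), mrna_log2fc = numeric(),
                      antisense = logical(), stringsAsFactors = FALSE)
    class(res) <- c("pair_table", "data.frame")
    return(res)
  }
  lnc <- ifelse(bt[e$from] == "lncRNA", e$from, e$to)
  mrna <- ifelse(bt[e$from] == "lncRNA", e$to, e$from)
  get_lfc <- function(id) {
    out <- unname(lfc[id])
    if (length(out) == 0) rep(NA_real_, length(id)) else out
  }
  res <- data.frame(
    lncrna_id = unname(lnc), lncrna_symbol = unname(sym[lnc]),
    lncrna_log2fc = get_lfc(lnc),
    mrna_id = unname(mrna), mrna_symbol = unname(sym[mrna]),
    mrna_log2fc = get_lfc(mrna),
    antisense = rep(NA, length(lnc)),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$lncrna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pair_table", "data.frame")
  res
}

#' Count mRNAs coexpressed with at least one lncRNA
#'
#' @param pairs a `pair_table` from [lncrna_mrna_pairs()].
#' @return list with `n_mrna` (distinct mRNAs in the table) and `n_mrna_up`
#'   (those with positive log2 fold change).
#' @export
count_coexpressed_mrnas <- function(pairs) {
  first <- !duplicated(pairs$mrna_id)
  list(n_mrna = sum(first),
       n_mrna_up = sum(first & pairs$mrna_log2fc > 0, na.rm = TRUE))
}

#' Flag antisense lncRNA--mRNA pairs
#'
#' A pair is antisense iff the two gene intervals overlap by at least
#' `min_overlap` bp on the same chromosome with opposite strands
#' (checked with GenomicRanges). Pairs with missing coordinates get an NA
#' flag with a warning.
#'
#' @param pairs a `pair_table`.
#' @param annotation annotation table with `chrom`, `start`, `end`,
#'   `strand`.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return the pair table with the `antisense` column filled.
#' @export
antisense_pairs <- function(pairs, annotation, min_overlap = 1) {
  if (nrow(pairs) == 0) return(pairs)
  ann <- annotation[match(c(pairs$lncrna_id, pairs$mrna_id),
                          annotation$gene_id), , drop = FALSE]
  n <- nrow(pairs)
  a1 <- ann[seq_len(n), , drop = FALSE]
  a2 <- ann[n + seq_len(n), , drop = FALSE]
  missing <- !complete.cases(a1[, c("chrom", "start", "end", "strand")]) |
    !complete.cases(a2[, c("chrom", "start", "end", "strand")])
  if (any(missing)) {
    warning(sum(missing), " pair(s) lack coordinates; antisense flag is NA")
  }
  flag <- rep(NA, n)
  ok <- !missing
  if (any(ok)) {
    sl <- unique(c(a1$chrom[ok], a2$chrom[ok]))
    gr1 <- GenomicRanges::GRanges(factor(a1$chrom[ok], levels = sl),
                                  IRanges::IRanges(a1$start[ok], a1$end[ok]),
                                  strand = a1$strand[ok])
    gr2 <- GenomicRanges::GRanges(factor(a2$chrom[ok], levels = sl),
                                  IRanges::IRanges(a2$start[ok], a2$end[ok]),
                                  strand = a2$strand[ok])
    ov <- IRanges::poverlaps(gr1, gr2, minoverlap = min_overlap,
                             ignore.strand = TRUE)
    opp <- as.character(GenomicRanges::strand(gr1)) !=
      as.character(GenomicRanges::strand(gr2)) &
      as.character(GenomicRanges::strand(gr1)) %in% c("+", "-") &
      as.character(GenomicRanges::strand(gr2)) %in% c("+", "-")
    flag[ok] <- as.logical(ov) & opp
  }
  pairs$antisense <- flag
  pairs
}

#' Export a network to SIF or GraphML
#'
#' SIF lines are `gene_a<TAB>coexp<TAB>gene_b` (isolated nodes, if any, as
#' bare single-field lines). GraphML (via igraph) carries node `biotype`
#' and edge `r`/`sign` attributes. [import_network()] on the written file
#' reproduces the node and edge sets exactly.
#'
#' @param net a `coex_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_argument("unknown format: ",
                                                       format[1]))
  if (format == "sif") {
    iso <- setdiff(net$nodes$gene_id, c(net$edges$from, net$edges$to))
    lines <- c(sprintf("%s\tcoexp\t%s", net$edges$from, net$edges$to), iso)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("from", "to", "r", "sign")], directed = FALSE,
      vertices = net$nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @param annotation optional annotation to restore biotype labels for SIF
#'   (which does not carry attributes).
#' @export
import_network <- function(path, format = c("sif", "graphml"),
                           annotation = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_argument("unknown format: ",
                                                       format[1]))
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t")
    is_edge <- lengths(parts) >= 3
    from <- vapply(parts[is_edge], `[`, "", 1)
    to <- vapply(parts[is_edge], `[`, "", 3)
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    ids <- sort(unique(c(from, to,
                         vapply(parts[!is_edge], `[`, "", 1))))
    bt <- if (!is.null(annotation)) {
      annotation$biotype[match(ids, annotation$gene_id)]
    } else {
      rep(NA_character_, length(ids))
    }
    nodes <- data.frame(gene_id = ids, biotype = bt,
                        stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vs <- igraph::vertex_attr(g)
    nodes <- data.frame(gene_id = vs$name,
                        biotype = vs$biotype %||% NA_character_,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    es <- igraph::edge_attr(g)
    from <- el[, 1]; to <- el[, 2]
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    edges <- data.frame(from = from, to = to,
                        r = es$r %||% NA_real_,
                        sign = es$sign %||% NA_integer_,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  }
  rownames(edges) <- rownames(nodes) <- NULL
  coex_network(nodes, edges)
}
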