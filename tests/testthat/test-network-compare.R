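mknet <- function(edges_chr, genes = NULL) {
  if (length(edges_chr)) {
    parts <- do.call(rbind, strsplit(edges_chr, "-"))
    edges <- data.frame(from = pmin(parts[, 1], parts[, 2]),
                        to = pmax(parts[, 1], parts[, 2]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character())
  }
  ids <- sort(unique(c(edges$from, edges$to, genes)))
  coex_network(data.frame(gene_id = ids, biotype = rep("mRNA", length(ids))),
               edges)
}

test_that("network set operations obey the set identities", {
  a <- mknet(c("x-y", "u-v"))
  expect_equal(nrow(network_difference(a, a)$edges), 0)
  d <- network_difference(a, mknet("u-v"))
  expect_equal(d$edges$from, "x")
  expect_equal(sort(d$nodes$gene_id), c("x", "y"))

  set.seed(7)
  genes <- sprintf("g%02d", 1:20)
  for (i in 1:20) {
    na <- random_network(genes, 0.2)
    nb <- random_network(genes, 0.2)
    ka <- paste(na$edges$from, na$edges$to)
    kb <- paste(nb$edges$from, nb$edges$to)
    d <- network_difference(na, nb)
    kd <- paste(d$edges$from, d$edges$to)
    expect_setequal(kd, setdiff(ka, kb))          # brute-force membership
    i_ <- network_difference(na, nb, "intersection")
    ki <- paste(i_$edges$from, i_$edges$to)
    expect_setequal(ki, intersect(ka, kb))
    expect_setequal(c(kd, ki), ka)                # (a-b) U (a^b) = a
    expect_length(intersect(kd, kb), 0)           # (a-b) ^ b = empty
    s <- network_difference(na, nb, "symmetric_difference")
    expect_setequal(paste(s$edges$from, s$edges$to),
                    union(setdiff(ka, kb), setdiff(kb, ka)))
  }
})

test_that("component census tallies size classes like union-find", {
  net <- mknet(c("a-b", "c-d", "e-f", "e-g", "h-i", "h-j", "h-k", "i-j",
                 "l-m", "l-n", "l-o", "l-p", "m-n", "o-p", "l-q", "m-q",
                 "n-q", "o-q", "p-q"))
  ann <- data.frame(gene_id = net$nodes$gene_id, biotype = "mRNA")
  cc <- component_census(net, ann, large_min = 6)
  expect_equal(cc$pairs, 2)
  expect_equal(cc$trios, 1)
  expect_equal(cc$quartets, 1)
  expect_equal(cc$large, 6)
  expect_equal(sum(cc$sizes), cc$n_nodes)

  empty <- mknet(character())
  cc0 <- component_census(empty, ann)
  expect_equal(cc0$n_nodes, 0)
  expect_equal(cc0$pairs + cc0$trios + cc0$quartets + cc0$quintets, 0)

  set.seed(8)
  genes <- sprintf("g%02d", 1:15)
  for (i in 1:30) {
    net <- random_network(genes, runif(1, 0.05, 0.3))
    ann <- data.frame(gene_id = net$nodes$gene_id, biotype = "mRNA")
    cc <- component_census(net, ann)
    sizes <- bf_components(net$nodes$gene_id, net$edges$from, net$edges$to)
    expect_setequal(cc$sizes, sizes)
  }

  expect_error(component_census(mknet("a-b"),
                                data.frame(gene_id = "a", biotype = "mRNA")),
               "biotype")
})

test_that("lncRNA-mRNA pair extraction counts distinct mRNAs", {
  fx <- table3_as_network()
  pairs <- lncrna_mrna_pairs(fx$network, fx$annotation, fx$de)
  expect_equal(nrow(pairs), 26)
  cnt <- count_coexpressed_mrnas(pairs)
  expect_equal(cnt$n_mrna, 24)
  expect_equal(cnt$n_mrna_up, 7)

  # a homogeneous network yields an empty pair table
  net <- mknet(c("a-b", "b-c"))
  ann <- data.frame(gene_id = c("a", "b", "c"), biotype = "mRNA",
                    symbol = c("A", "B", "C"))
  expect_equal(nrow(lncrna_mrna_pairs(net, ann)), 0)
})

test_that("antisense detection requires overlap and opposite strands", {
  ann <- generate_annotation(6, 6, 2, seed = 9)
  lnc <- ann$gene_id[ann$biotype == "lncRNA"]
  mrna <- ann$gene_id[ann$biotype == "mRNA"]
  pairs <- data.frame(lncrna_id = lnc[1:4], lncrna_symbol = NA,
                      lncrna_log2fc = NA, mrna_id = mrna[1:4],
                      mrna_symbol = NA, mrna_log2fc = NA, antisense = NA)
  class(pairs) <- c("pair_table", "data.frame")
  out <- antisense_pairs(pairs, ann)
  expect_equal(out$antisense, c(TRUE, TRUE, FALSE, FALSE))

  # same-strand overlap is not antisense
  ann2 <- data.frame(gene_id = c("L", "M"), symbol = c("L", "M"),
                     biotype = c("lncRNA", "mRNA"), chrom = "chr1",
                     start = c(100, 150), end = c(300, 400),
                     strand = c("+", "+"))
  p2 <- pairs[1, ]
  p2$lncrna_id <- "L"; p2$mrna_id <- "M"
  expect_false(antisense_pairs(p2, ann2)$antisense)
  ann2$strand <- c("+", "-")
  expect_true(antisense_pairs(p2, ann2)$antisense)
  ann2$chrom <- c("chr1", "chr2")
  expect_false(antisense_pairs(p2, ann2)$antisense)

  # missing coordinates give NA with a warning
  ann3 <- ann2
  ann3$start[1] <- NA
  expect_warning(out3 <- antisense_pairs(p2, ann3), "coordinates")
  expect_true(is.na(out3$antisense))
})

test_that("SIF and GraphML exports round-trip node and edge sets", {
  tmp <- withr::local_tempdir()
  empty <- mknet(character())
  export_network(empty, file.path(tmp, "e.sif"), "sif")
  back <- import_network(file.path(tmp, "e.sif"), "sif")
  expect_equal(nrow(back$edges), 0)

  path3 <- mknet(c("a-b", "b-c"))
  export_network(path3, file.path(tmp, "p.sif"), "sif")
  expect_length(readLines(file.path(tmp, "p.sif")), 2)

  set.seed(10)
  genes <- sprintf("g%02d", 1:12)
  for (i in 1:5) {
    net <- random_network(genes, 0.25)
    net$edges$r <- runif(nrow(net$edges), -1, 1)
    net$edges$sign <- ifelse(net$edges$r >= 0, 1L, -1L)
    for (fmt in c("sif", "graphml")) {
      f <- file.path(tmp, paste0("n.", fmt))
      export_network(net, f, fmt)
      back <- import_network(f, fmt)
      expect_setequal(back$nodes$gene_id, net$nodes$gene_id)
      expect_setequal(paste(back$edges$from, back$edges$to),
                      paste(net$edges$from, net$edges$to))
    }
  }
  expect_error(export_network(path3, file.path(tmp, "x"), "dot"),
               "unknown format")
})
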