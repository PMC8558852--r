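test_that("generate_annotation plants exactly the requested antisense pairs", {
  expect_equal(nrow(generate_annotation(0, 0, 0, seed = 1)), 0)
  expect_error(generate_annotation(-1, 5), "non-negative")
  expect_error(generate_annotation(2, 2, 3), "n_antisense_pairs")

  ann <- generate_annotation(5, 5, 2, seed = 7)
  expect_equal(nrow(ann), 10)
  expect_equal(sum(ann$biotype == "lncRNA"), 5)
  # exhaustive pairwise check of the overlap-and-opposite-strand predicate
  hits <- 0
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(ann))) {
      if (ann$biotype[i] != "lncRNA" || ann$biotype[j] != "mRNA") next
      same_chr <- ann$chrom[i] == ann$chrom[j]
      overlap <- ann$start[i] <= ann$end[j] & ann$start[j] <= ann$end[i]
      opposite <- ann$strand[i] != ann$strand[j]
      if (same_chr && overlap && opposite) hits <- hits + 1
    }
  }
  expect_equal(hits, 2)
  # all other intervals pairwise disjoint
  n_overlapping <- 0
  for (i in seq_len(nrow(ann) - 1)) {
    for (j in (i + 1):nrow(ann)) {
      if (ann$chrom[i] == ann$chrom[j] &&
          ann$start[i] <= ann$end[j] && ann$start[j] <= ann$end[i]) {
        n_overlapping <- n_overlapping + 1
      }
    }
  }
  expect_equal(n_overlapping, 2)
  # determinism
  expect_identical(ann, generate_annotation(5, 5, 2, seed = 7))
})

test_that("annotation without planted overlaps yields no antisense flags", {
  ann <- generate_annotation(100, 50, 0, seed = 1)
  pairs <- data.frame(
    lncrna_id = ann$gene_id[ann$biotype == "lncRNA"][1:20],
    lncrna_symbol = NA, lncrna_log2fc = NA,
    mrna_id = ann$gene_id[ann$biotype == "mRNA"][1:20],
    mrna_symbol = NA, mrna_log2fc = NA, antisense = NA
  )
  class(pairs) <- c("pair_table", "data.frame")
  flagged <- antisense_pairs(pairs, ann)
  expect_false(any(flagged$antisense))
})

test_that("generate_counts is reproducible and negative-binomial shaped", {
  ann <- generate_annotation(80, 40, 0, seed = 1)
  params <- count_sim_params(de_fraction = 0.3, modules = list(
    list(size = 8, target_r = 0.8, cohorts = "tumorA")
  ))
  sim1 <- generate_counts(cohort_design(10, 10, 10,
                                        gleason = c("6" = 5, "7" = 5)),
                          ann, params, seed = 11)
  sim2 <- generate_counts(cohort_design(10, 10, 10,
                                        gleason = c("6" = 5, "7" = 5)),
                          ann, params, seed = 11)
  expect_identical(sim1$counts$counts, sim2$counts$counts)
  expect_identical(sim1$truth$de, sim2$truth$de)
  m <- sim1$counts$counts
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  expect_equal(dim(m), c(120, 30))
  # overdispersion: pooled variance exceeds mean for the bulk of genes
  null_genes <- sim1$truth$de$gene_id[sim1$truth$de$lfc_tumorA == 0]
  null_genes <- setdiff(null_genes,
                        unlist(lapply(sim1$truth$modules, `[[`, "members")))
  mu <- rowMeans(m[null_genes, ])
  v <- apply(m[null_genes, ], 1, var)
  big <- mu > 50
  expect_gt(mean(v[big] > mu[big]), 0.9)
})

test_that("null generator produces uncorrelated genes", {
  # the null mean |r| of Pearson correlation is ~ sqrt(2/pi)/sqrt(n-1),
  # i.e. ~0.115 at n = 49 and ~0.081 at n = 98; check both regimes
  # enough genes that CPM's compositional coupling is negligible
  ann <- generate_annotation(200, 100, 0, seed = 2)
  params <- count_sim_params(de_fraction = 0, modules = list())
  stats <- sapply(1:5, function(s) {
    sim <- generate_counts(cohort_design(49, 49, 0, gleason = c("7" = 49)),
                           ann, params, seed = s)
    x <- log_cpm(sim$counts)
    ca <- sim$counts$sample_meta$cohort == "tumorA"
    r49 <- pearson_similarity(x[1:10, ca])
    r98 <- pearson_similarity(x[1:10, ])
    c(mean(abs(r49[upper.tri(r49)])), mean(abs(r98[upper.tri(r98)])))
  })
  expect_lt(mean(stats[1, ]), 0.15)
  expect_lt(mean(stats[2, ]), 0.1)
})

test_that("a cohort-specific module raises correlations only in its cohort", {
  ann <- generate_annotation(40, 20, 0, seed = 3)
  params <- count_sim_params(de_fraction = 0.5, modules = list(
    list(size = 10, target_r = 0.8, cohorts = "tumorA")
  ))
  sim <- generate_counts(cohort_design(), ann, params, seed = 4)
  x <- log_cpm(sim$counts)
  members <- sim$truth$modules[[1]]$members
  meta <- sim$counts$sample_meta
  r_a <- pearson_similarity(x[members, meta$cohort == "tumorA"])
  r_b <- pearson_similarity(x[members, meta$cohort == "tumorB"])
  gap <- mean(abs(r_a[upper.tri(r_a)])) - mean(abs(r_b[upper.tri(r_b)]))
  expect_gt(gap, 0.4)
})

test_that("planted log2 fold changes translate to mean count ratios", {
  ann <- generate_annotation(150, 0, 0, seed = 5)
  params <- count_sim_params(de_fraction = 0.4, de_lfc_range = c(1, 1),
                             modules = list(), hazard_hr = NULL)
  sim <- generate_counts(cohort_design(), ann, params, seed = 6)
  m <- sim$counts$counts
  meta <- sim$counts$sample_meta
  lib <- colSums(m)
  norm <- sweep(m, 2, lib / mean(lib), "/")
  up <- sim$truth$de$gene_id[sim$truth$de$lfc_tumorA == 1]
  ratio <- rowMeans(norm[up, meta$cohort == "tumorA"]) /
    rowMeans(norm[up, meta$cohort == "normal"])
  expect_equal(mean(ratio), 2, tolerance = 0.1)
})

test_that("generate_survival honors censoring and hazard arguments", {
  grp <- rep(c("high", "low"), 50)
  s0 <- generate_survival(grp, hr = 1, censor_rate = 0, seed = 1)
  expect_true(all(s0$event == 1))
  expect_identical(s0, generate_survival(grp, hr = 1, censor_rate = 0,
                                         seed = 1))
  expect_error(generate_survival(grp, hr = 0), "positive")
  expect_error(generate_survival(grp, hr = -2), "positive")
  s1 <- generate_survival(grp, hr = 4, baseline_hazard = 1e-3,
                          censor_rate = 0, seed = 2)
  expect_lt(median(s1$time[grp == "high"]), median(s1$time[grp == "low"]))
})

test_that("packaged fixtures parse to the published row sets", {
  t2 <- load_fixture("table2")
  expect_equal(sum(t2$biotype == "mRNA"), 8)
  expect_equal(sum(t2$biotype == "lncRNA"), 22)

  t3 <- load_fixture("table3")
  row <- t3[t3$lncrna_symbol %in% "ACTA2-AS1" & t3$mrna_symbol %in% "KCNMB1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$lncrna_log2fc, -2.51)
  expect_equal(row$mrna_log2fc, -2.79)

  venn <- load_fixture("venn_counts")
  expect_equal(venn$size_a[venn$category == "mrna_up"], 702)
  expect_equal(venn$shared[venn$category == "mrna_up"], 489)

  expect_error(load_fixture("nonexistent"), "unknown fixture")
})
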