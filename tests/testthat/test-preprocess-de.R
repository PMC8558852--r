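test_that("cpm normalizes columns to one million with unit factors", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.numeric(cpm(m)), c(250000, 750000))

  set.seed(1)
  m2 <- matrix(rpois(200, 30), 20, 10,
               dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  expect_equal(unname(colSums(cpm(m2))), rep(1e6, 10))
  m3 <- m2
  m3[, 4] <- m3[, 4] * 2
  expect_equal(cpm(m3)[, 4], cpm(m2)[, 4])

  m0 <- m2
  m0[, 2] <- 0
  expect_error(cpm(m0), "s2")
})

test_that("low-expression filter matches the per-gene predicate", {
  # boundary: CPM > 1 in exactly half the samples is kept
  m <- matrix(0, 2, 98, dimnames = list(c("edge", "zero"), NULL))
  m[1, 1:49] <- 1000
  # a filler gene keeps every library size positive
  m <- rbind(m, filler = 1000)
  kept <- filter_low_expression(m)
  expect_true("edge" %in% rownames(kept))
  expect_false("zero" %in% rownames(kept))

  set.seed(42)
  big <- matrix(rnbinom(200 * 20, mu = 5, size = 2), 200, 20,
                dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:20)))
  big[1, ] <- big[1, ] + 1  # avoid an all-zero library edge case
  kept2 <- rownames(filter_low_expression(big, 1, 0.5))
  cc <- cpm(big)
  oracle <- rownames(big)[vapply(seq_len(200), function(i) {
    mean(cc[i, ] > 1) >= 0.5
  }, TRUE)]
  expect_identical(kept2, oracle)

  expect_equal(nrow(filter_low_expression(big[0, , drop = FALSE])), 0)
})

test_that("TMM factors remove depth differences and match the formula", {
  set.seed(7)
  base <- rnbinom(500, mu = 100, size = 5) + 1
  same <- matrix(rep(base, 4), 500, 4,
                 dimnames = list(NULL, sprintf("s%d", 1:4)))
  expect_equal(unname(tmm_factors(same)), rep(1, 4), tolerance = 1e-9)

  scaled <- sweep(same, 2, c(1, 2, 0.5, 4), "*")
  expect_true(all(abs(tmm_factors(scaled) - 1) < 0.02))

  # sample 2 has 5% of genes 8-fold inflated: factor should match a direct
  # implementation of the doubly-trimmed weighted mean
  noisy <- matrix(rnbinom(500 * 4, mu = base, size = 50), 500, 4,
                  dimnames = list(NULL, sprintf("s%d", 1:4)))
  idx <- sample(500, 25)
  noisy[idx, 2] <- noisy[idx, 2] * 8
  f <- tmm_factors(noisy)
  bf <- bf_tmm_factor(noisy[, 2], noisy[, 1])
  ratio <- (f[2] / f[1])
  expect_equal(unname(ratio), bf, tolerance = 0.05)

  expect_error(tmm_factors(same[, 1, drop = FALSE]), "2 samples")
})

test_that("log_cpm follows its closed form and is monotone", {
  m <- matrix(c(0, 10), 2, 1)
  m <- rbind(m, 1e6 - 10)  # library size 1e6
  lc <- log_cpm(m, prior_count = 0.5)
  expect_equal(lc[1, 1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-9)
  expect_equal(lc[1, 1], -1.0000014, tolerance = 1e-6)
  expect_lt(lc[1, 1], lc[2, 1])
  # converges to log2(CPM) for large counts
  big <- matrix(c(5000, 995000), 2, 1)
  expect_equal(log_cpm(big)[1, 1], log2(cpm(big))[1, 1], tolerance = 0.01)
  expect_error(log_cpm(m, prior_count = 0), "positive")
})

test_that("fit_de handles degenerate genes and rank-deficient designs", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:12),
                     cohort = rep(c("tumorA", "normal"), each = 6),
                     gleason = c(rep(7, 6), rep(0, 6)))
  set.seed(1)
  x <- matrix(rnorm(10 * 12, 5), 10, 12,
              dimnames = list(sprintf("g%d", 1:10), meta$sample_id))
  x[1, ] <- 3  # flat gene
  de <- fit_de(x, meta, "tumorA", "normal", gleason_covariate = FALSE)
  expect_equal(de$log2fc[1], 0)
  expect_equal(de$p_raw[1], 1)

  # constant gleason within a two-cohort contrast is confounded with the
  # intercept after centering: all-zero column -> rank deficiency
  meta2 <- meta
  meta2$gleason <- 0
  expect_error(fit_de(x, meta2, "tumorA", "normal"), "gleason")
})

test_that("fit_de is calibrated on null data and detects planted effects", {
  ann <- generate_annotation(2000, 0, 0, seed = 10)
  params <- count_sim_params(de_fraction = 0, modules = list(),
                             hazard_hr = NULL)
  sim <- generate_counts(cohort_design(), ann, params, seed = 10)
  x <- log_cpm(sim$counts, tmm_factors(sim$counts))
  de <- fit_de(x, sim$counts$sample_meta, "tumorA", "normal")
  expect_gt(mean(de$p_raw < 0.05), 0.03)
  expect_lt(mean(de$p_raw < 0.05), 0.07)

  # planted effect at the canonical 1.5 log2FC is found and selected
  params2 <- count_sim_params(de_fraction = 0.1,
                              de_lfc_range = c(1.5, 1.5),
                              modules = list(), hazard_hr = NULL)
  ann2 <- generate_annotation(500, 0, 0, seed = 11)
  sim2 <- generate_counts(cohort_design(), ann2, params2, seed = 11)
  x2 <- log_cpm(sim2$counts, tmm_factors(sim2$counts))
  de2 <- fit_de(x2, sim2$counts$sample_meta, "tumorA", "normal")
  sel <- select_de(de2, ann2)
  planted <- sim2$truth$de$gene_id[sim2$truth$de$lfc_tumorA != 0]
  found <- unlist(unclass(sel)[1:4])
  expect_gt(mean(planted %in% found), 0.9)
})

test_that("bh_fdr implements the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_fdr(p), bf_bh(p))
  }
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("select_de applies the fold-change and FDR rule per biotype", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    biotype = c("mRNA", "lncRNA", "mRNA", "lncRNA"))
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(0.9, -2.51, 1.8, 1.2),
                   fdr = c(0.001, 1.53e-8, 0.5, 0.004))
  sel <- select_de(de, ann)
  expect_false("a" %in% unlist(unclass(sel)[1:4]))  # linear FC 1.87 < 2
  expect_true("b" %in% sel$lncrna_down)
  expect_false("c" %in% sel$mrna_up)  # fails FDR
  expect_true("d" %in% sel$lncrna_up)

  # degenerate thresholds select everything with fdr < 1
  sel_all <- select_de(de, ann, fc_linear = 1, fdr_max = 1)
  expect_setequal(unlist(unclass(sel_all)[1:4]), c("a", "b", "c", "d"))

  expect_error(select_de(de, ann[1:2, ]), "biotype")
})

test_that("overlap_summary computes exact intersections and percentages", {
  a <- list(up = c("x", "y", "z"), down = c("p", "q"))
  b <- list(up = c("x", "y", "z"), down = c("r", "s"))
  ov <- overlap_summary(a, b)
  expect_equal(ov$shared, c(3, 0))
  expect_equal(ov$pct_a_shared, c(100, 0))
  # percentage is round-half-up at one decimal
  df <- data.frame(size_a = 702, size_b = 600, shared = 489)
  expect_equal(overlap_summary(df)$pct_a_shared, 69.7)
})

test_that("match_cohorts matches stratum counts and is deterministic", {
  a <- data.frame(sample_id = sprintf("a%d", 1:12),
                  gleason = rep(c(6, 7), c(9, 3)))
  b <- data.frame(sample_id = sprintf("b%d", 1:40),
                  gleason = rep(c(6, 7, 8), c(20, 10, 10)))
  m <- match_cohorts(a, b, seed = 5)
  expect_equal(nrow(m), 12)
  expect_equal(sum(m$gleason == 6), 9)
  expect_equal(sum(m$gleason == 7), 3)
  expect_identical(m, match_cohorts(a, b, seed = 5))
  expect_equal(nrow(match_cohorts(a[0, ], b)), 0)
  a2 <- data.frame(sample_id = "a1", gleason = 10)
  expect_error(match_cohorts(a2, b), "gleason=10")
})
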