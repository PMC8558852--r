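as_count_mat <- function(counts) {
  if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
}

#' Counts per million
#'
#' `cpm_ij = 1e6 * count_ij / (library_size_j * factor_j)` where the library
#' size is the column sum. With unit factors every CPM column sums to 1e6.
#'
#' @param counts integer matrix (genes x samples) or a [count_matrix()].
#' @param factors optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); default 1.
#' @export
cpm <- function(counts, factors = NULL) {
  m <- as_count_mat(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    bad <- colnames(m)[lib == 0] %||% which(lib == 0)
    stop_argument("zero library size for sample(s): ",
                  paste(bad, collapse = ", "))
  }
  if (is.null(factors)) factors <- rep(1, ncol(m))
  sweep(m, 2, lib * factors, "/") * 1e6
}

#' Filter genes below an expression floor
#'
#' Keeps a gene iff its CPM exceeds `min_cpm` in at least `min_fraction` of
#' all samples; gene order is preserved.
#'
#' @inheritParams cpm
#' @param min_cpm CPM cutoff (default 1).
#' @param min_fraction minimum fraction of samples above the cutoff
#'   (default 0.5).
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_fraction = 0.5) {
  if (min_fraction < 0 || min_fraction > 1) {
    stop_argument("min_fraction must be in [0, 1]")
  }
  m <- as_count_mat(counts)
  if (nrow(m) == 0 || ncol(m) == 0) return(counts)
  keep <- rowMeans(cpm(m) > min_cpm) >= min_fraction
  if (inherits(counts, "count_matrix")) {
    count_matrix(m[keep, , drop = FALSE], counts$sample_meta)
  } else {
    m[keep, , drop = FALSE]
  }
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack), computed
#' by edgeR: the reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper quartile; per sample the log2 ratios (M) and
#' average log2 abundances (A) versus the reference are doubly trimmed and
#' the factor is `2^(weighted mean M)` with inverse-asymptotic-variance
#' weights, rescaled so factors have geometric mean 1.
#'
#' @inheritParams cpm
#' @param trim_m two-sided trim fraction on M values (default 0.3).
#' @param trim_a two-sided trim fraction on A values (default 0.05).
#' @return named per-sample factor vector.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  m <- as_count_mat(counts)
  if (ncol(m) < 2) stop_argument("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(as.numeric(f), colnames(m))
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + prior) / (lib * factor + 2 * prior) * 1e6)`; the prior
#' damps the variance of low counts and keeps zeros finite.
#'
#' @inheritParams cpm
#' @param prior_count positive prior added to each count (default 0.5).
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  if (prior_count <= 0) stop_argument("prior_count must be positive")
  m <- as_count_mat(counts)
  lib <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  eff <- lib * factors
  log2(sweep(m + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}

#' Moderated-t differential expression
#'
#' Fits, per gene, an ordinary least-squares model on log-CPM with
#' intercept + tumor indicator + ordinal Gleason covariate (reference
#' samples without a grade are coded 0), and tests the tumor coefficient
#' with an empirical-Bayes moderated t: gene variances are shrunk toward a
#' common prior `s0^2` with prior df `d0`, both estimated by moment
#' matching on the log sample variances (limma's eBayes). Voom precision
#' weights are deliberately not used; this is a log-CPM "trend-free"
#' moderated t.
#'
#' @param logcpm numeric matrix genes x samples (e.g. from [log_cpm()]).
#' @param sample_meta data.frame with `sample_id`, `cohort`, `gleason`
#'   aligned to `logcpm` columns.
#' @param cohort the case cohort label (e.g. `"tumorA"`).
#' @param reference the reference cohort label (default `"normal"`).
#' @param gleason_covariate include the Gleason ordinal covariate
#'   (default TRUE).
#' @return a `de_table` data.frame: `gene_id`, `log2fc`, `t`, `p_raw`,
#'   `fdr`, `direction`.
#' @export
fit_de <- function(logcpm, sample_meta, cohort, reference = "normal",
                   gleason_covariate = TRUE) {
  sel <- sample_meta$cohort %in% c(cohort, reference)
  meta <- sample_meta[sel, , drop = FALSE]
  x <- logcpm[, sel, drop = FALSE]
  is_case <- as.integer(meta$cohort == cohort)
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop_argument("need at least 2 samples per level of the primary factor")
  }
  design <- cbind(intercept = 1, tumor = is_case)
  if (gleason_covariate) {
    gs <- meta$gleason
    gs[is.na(gs)] <- 0
    # center the ordinal grade within graded samples (ungraded reference
    # samples stay 0) so the covariate is orthogonal to the tumor
    # indicator instead of nearly collinear with it
    graded <- gs > 0
    if (any(graded)) gs[graded] <- gs[graded] - mean(gs[graded])
    design <- cbind(design, gleason = gs)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    confounded <- setdiff(colnames(design),
                          colnames(design)[qr_d$pivot[seq_len(qr_d$rank)]])
    stop_argument("rank-deficient design; confounded column(s): ",
                  paste(confounded, collapse = ", "))
  }
  fit <- limma::lmFit(x, design)
  fit <- limma::eBayes(fit)
  lfc <- fit$coefficients[, "tumor"]
  p <- fit$p.value[, "tumor"]
  # degenerate-variance convention: a flat gene is a definite non-finding
  flat <- fit$sigma == 0 & abs(lfc) < 1e-12
  p[flat] <- 1
  res <- data.frame(gene_id = rownames(x),
                    log2fc = as.numeric(lfc),
                    t = as.numeric(fit$t[, "tumor"]),
                    p_raw = as.numeric(p),
                    fdr = bh_fdr(as.numeric(p)),
                    direction = ifelse(lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  class(res) <- c("de_table", "data.frame")
  res
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up BH adjustment, clipped to 1.
#'
#' @param p vector of probabilities in \[0, 1\].
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p))) stop_argument("p-values must be finite")
  if (any(p < 0 | p > 1)) stop_argument("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Apply the DE selection rule and partition by direction and biotype
#'
#' A gene is selected iff `|log2fc| > log2(fc_linear)` and `fdr < fdr_max`
#' (defaults: linear fold change 2, FDR 0.01).
#'
#' @param de a `de_table` from [fit_de()] (columns `gene_id`, `log2fc`,
#'   `fdr`).
#' @param annotation annotation table supplying `biotype` per gene.
#' @param fc_linear linear fold-change bound (default 2).
#' @param fdr_max FDR bound (default 0.01).
#' @return list with character vectors `mrna_up`, `mrna_down`, `lncrna_up`,
#'   `lncrna_down`; the selected-annotated table is attached as attribute
#'   `"table"`.
#' @export
select_de <- function(de, annotation, fc_linear = 2, fdr_max = 0.01) {
  bt <- annotation$biotype[match(de$gene_id, annotation$gene_id)]
  if (anyNA(bt)) {
    stop_argument("genes without biotype: ",
                  paste(head(de$gene_id[is.na(bt)], 10), collapse = ", "))
  }
  selected <- abs(de$log2fc) > log2(fc_linear) & de$fdr < fdr_max
  tab <- cbind(de, biotype = bt, selected = selected)
  pick <- function(b, up) {
    de$gene_id[selected & bt == b & ((de$log2fc > 0) == up)]
  }
  structure(list(mrna_up = pick("mRNA", TRUE),
                 mrna_down = pick("mRNA", FALSE),
                 lncrna_up = pick("lncRNA", TRUE),
                 lncrna_down = pick("lncRNA", FALSE)),
            table = tab, class = "de_selection")
}

#' Overlap summary between two DE gene-set collections
#'
#' Given matched named lists of gene-id sets (or a data.frame of
#' per-category counts with columns `size_a`, `size_b`, `shared`),
#' reports per category the set sizes, the intersection size, and the
#' shared percentages `100 * shared / size` rounded half-up to one decimal
#' (0 when the set is empty).
#'
#' @param sets_a,sets_b named lists of character vectors with matching
#'   names, or `sets_a` a data.frame of counts (then `sets_b` is ignored).
#' @export
overlap_summary <- function(sets_a, sets_b = NULL) {
  if (is.data.frame(sets_a)) {
    df <- sets_a
    stopifnot(all(c("size_a", "size_b", "shared") %in% names(df)))
  } else {
    stopifnot(identical(names(sets_a), names(sets_b)))
    df <- data.frame(
      category = names(sets_a),
      size_a = vapply(sets_a, length, 1L),
      size_b = vapply(sets_b, length, 1L),
      shared = mapply(function(a, b) length(intersect(a, b)),
                      sets_a, sets_b),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (any(df$shared > pmin(df$size_a, df$size_b))) {
    stop_argument("shared exceeds a set size; sets must contain unique ids")
  }
  df$pct_a_shared <- ifelse(df$size_a > 0,
                            round_half_up(100 * df$shared / df$size_a, 1), 0)
  df$pct_b_shared <- ifelse(df$size_b > 0,
                            round_half_up(100 * df$shared / df$size_b, 1), 0)
  df
}

#' Match a comparison cohort to a case cohort on a stratification key
#'
#' For every value of the key in `samples_a`, draws the same number of
#' samples uniformly without replacement from `samples_b` within that
#' stratum (1:1 frequency matching).
#'
#' @param samples_a,samples_b data.frames with `sample_id` and the key
#'   column.
#' @param key stratification column name (default `"gleason"`).
#' @param seed integer seed.
#' @return the matched subset of `samples_b` (same columns, `|a|` rows).
#' @export
match_cohorts <- function(samples_a, samples_b, key = "gleason", seed = 1) {
  if (nrow(samples_a) == 0) return(samples_b[0, , drop = FALSE])
  set.seed(seed)
  need <- table(samples_a[[key]])
  picked <- integer()
  for (v in names(need)) {
    avail <- which(as.character(samples_b[[key]]) == v)
    if (length(avail) < need[[v]]) {
      stop_argument("stratum ", key, "=", v, ": need ", need[[v]],
                    " samples, only ", length(avail), " available")
    }
    picked <- c(picked, sample(avail, need[[v]]))
  }
  samples_b[sort(picked), , drop = FALSE]
}
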