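#' Generate a synthetic gene annotation with planted antisense pairs
#'
#' Builds an annotation table of mRNA and lncRNA loci laid out on autosomes
#' with non-overlapping intervals, except for a requested number of antisense
#' lncRNA--mRNA pairs: for each such pair the lncRNA interval is placed inside
#' the partner mRNA's interval on the opposite strand, so that exactly
#' `n_antisense_pairs` (lncRNA, mRNA) pairs satisfy the
#' overlap-and-opposite-strand predicate used by [antisense_pairs()].
#'
#' @param n_mrna number of protein-coding genes.
#' @param n_lncrna number of long non-coding genes.
#' @param n_antisense_pairs number of planted antisense lncRNA--mRNA pairs;
#'   must not exceed `min(n_mrna, n_lncrna)`.
#' @param seed integer seed for the layout RNG.
#' @return a data.frame with columns `gene_id`, `symbol`, `biotype`
#'   (`"mRNA"`/`"lncRNA"`), `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`.
#' @export
generate_annotation <- function(n_mrna, n_lncrna, n_antisense_pairs = 0,
                                seed = 1) {
  if (any(c(n_mrna, n_lncrna, n_antisense_pairs) < 0)) {
    stop_argument("gene and pair counts must be non-negative")
  }
  if (n_antisense_pairs > min(n_mrna, n_lncrna)) {
    stop_argument("n_antisense_pairs must not exceed min(n_mrna, n_lncrna)")
  }
  empty <- data.frame(
    gene_id = character(), symbol = character(), biotype = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), stringsAsFactors = FALSE
  )
  n <- n_mrna + n_lncrna
  if (n == 0) return(empty)
  set.seed(seed)

  biotype <- c(rep("mRNA", n_mrna), rep("lncRNA", n_lncrna))
  gene_id <- c(sprintf("ENSG%011d", seq_len(n_mrna)),
               sprintf("ENSG%011d", 5e8 + seq_len(n_lncrna)))
  symbol <- c(sprintf("MRNA%d", seq_len(n_mrna)),
              sprintf("LINC%04d", seq_len(n_lncrna)))

  chroms <- paste0("chr", 1:22)
  chrom <- character(n)
  start <- integer(n)
  end <- integer(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # lay out non-paired genes sequentially per chromosome with wide gaps
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  place <- function(len) {
    cc <- sample(chroms, 1)
    s <- cursor[[cc]] + sample(10000:100000, 1)
    cursor[[cc]] <<- s + len
    list(chrom = cc, start = s, end = s + len - 1L)
  }
  for (i in seq_len(n_mrna)) {
    loc <- place(sample(5000:50000, 1))
    chrom[i] <- loc$chrom; start[i] <- loc$start; end[i] <- loc$end
  }
  # antisense lncRNAs: nested inside the partner mRNA, opposite strand
  for (j in seq_len(n_lncrna)) {
    i <- n_mrna + j
    if (j <= n_antisense_pairs) {
      m <- j  # partner mRNA index
      len_m <- end[m] - start[m] + 1L
      len <- max(200L, as.integer(len_m * runif(1, 0.2, 0.8)))
      s <- start[m] + sample.int(len_m - len, 1)
      chrom[i] <- chrom[m]
      start[i] <- s
      end[i] <- s + len - 1L
      strand[i] <- if (strand[m] == "+") "-" else "+"
    } else {
      loc <- place(sample(1000:20000, 1))
      chrom[i] <- loc$chrom; start[i] <- loc$start; end[i] <- loc$end
    }
  }
  data.frame(gene_id = gene_id, symbol = symbol, biotype = biotype,
             chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Cohort design for the count generator
#'
#' Sample sizes and the per-cohort Gleason-sum distribution. The defaults
#' reproduce the study conditions: 49 tumor samples per cohort, 44 normals,
#' and Gleason sums 6:9, 7:33, 8:2, 9:4, 10:1 matched 1:1 across the two
#' tumor cohorts.
#'
#' @param n_tumor_a,n_tumor_b,n_normal sample counts per cohort.
#' @param gleason named integer vector (names = Gleason sum) giving the
#'   per-tumor-cohort distribution; must sum to the cohort size.
#' @export
cohort_design <- function(n_tumor_a = 49, n_tumor_b = 49, n_normal = 44,
                          gleason = c("6" = 9, "7" = 33, "8" = 2,
                                      "9" = 4, "10" = 1)) {
  if (any(c(n_tumor_a, n_tumor_b, n_normal) < 0)) {
    stop_argument("cohort sizes must be non-negative")
  }
  if (n_tumor_a > 0 && sum(gleason) != n_tumor_a) {
    stop_argument("gleason distribution must sum to the tumor cohort size")
  }
  if (n_tumor_a > 0 && n_tumor_b > 0 && n_tumor_a != n_tumor_b) {
    stop_argument("tumor cohorts must be the same size (1:1 matched design)")
  }
  structure(list(n_tumor_a = n_tumor_a, n_tumor_b = n_tumor_b,
                 n_normal = n_normal, gleason = gleason),
            class = "cohort_design")
}

#' Settings for the negative-binomial count generator
#'
#' @param baseline_log_mean mean of per-gene baseline natural-log means.
#' @param baseline_log_sd sd of per-gene baseline log means.
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`); 0 gives Poisson counts.
#' @param lib_size_range library-size scale factors are drawn log-uniformly
#'   from this interval (relative to nominal depth).
#' @param de_fraction fraction of genes planted as differentially expressed
#'   between tumor and normal.
#' @param de_lfc_range magnitude range of planted tumor-vs-normal log2 fold
#'   changes; the lower bound of 1 keeps every planted gene past the linear
#'   fold-change-2 selection rule.
#' @param de_shared_fraction fraction of planted DE genes sharing the same
#'   effect in both tumor cohorts (the rest are cohort-A-specific).
#' @param modules list of module specs, each
#'   `list(size =, cohorts =, target_r =)` or
#'   `list(size =, cohorts =, loading =)`; `cohorts` is a character vector
#'   of cohorts where the module's latent factor is active. With
#'   `target_r` (default 0.8) the per-gene loading is calibrated as
#'   `w_g = sqrt(r/(1-r) * (phi + 1/mu_g))`, the loading that yields
#'   within-module log-scale correlation near `r` given the gene's
#'   negative-binomial noise; an explicit `loading` overrides this.
#' @param modules_from_de if TRUE module members are drawn from the shared
#'   planted DE genes, so they survive a DE-based gene-list step.
#' @param module_min_mu minimum expected tumor-cohort mean count for a
#'   gene to be eligible as a module member (default 10): coexpression
#'   planted on genes below the detection floor is not recoverable by any
#'   method and would not pass the expression filter anyway.
#' @param hazard_hr planted hazard ratio (high vs low expression of the
#'   hazard gene) for simulated survival; NULL disables survival planting.
#' @param baseline_hazard,censor_rate exponential event / censoring rates
#'   per day.
#' @export
count_sim_params <- function(baseline_log_mean = log(150),
                             baseline_log_sd = 1.2,
                             dispersion = 0.2,
                             lib_size_range = c(0.5, 2),
                             de_fraction = 0.1,
                             de_lfc_range = c(1, 2.5),
                             de_shared_fraction = 0.8,
                             modules = list(
                               list(size = 10, target_r = 0.8,
                                    cohorts = c("tumorA", "tumorB")),
                               list(size = 10, target_r = 0.8,
                                    cohorts = c("tumorA", "tumorB")),
                               list(size = 10, target_r = 0.8,
                                    cohorts = "tumorA")
                             ),
                             modules_from_de = TRUE,
                             module_min_mu = 10,
                             hazard_hr = 2,
                             baseline_hazard = 1e-3,
                             censor_rate = 5e-4) {
  if (dispersion < 0) stop_argument("dispersion must be >= 0")
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0)) {
    stop_argument("lib_size_range must be two positive numbers")
  }
  structure(list(baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 de_fraction = de_fraction,
                 de_lfc_range = de_lfc_range,
                 de_shared_fraction = de_shared_fraction,
                 modules = modules,
                 modules_from_de = modules_from_de,
                 module_min_mu = module_min_mu,
                 hazard_hr = hazard_hr,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate),
            class = "count_sim_params")
}

#' Generate negative-binomial counts with planted DE genes and modules
#'
#' Counts for gene g in sample s are drawn as
#' `NB(mu_gs, phi)` with
#' `mu_gs = L_s * exp(b_g + log(2) * d_g(cohort_s) + sum_m w_gm z_ms)`,
#' where `L_s` is a log-uniform library-size scale, `b_g` a Gaussian
#' baseline, `d_g` the planted tumor-vs-normal log2 fold change for the
#' sample's cohort, and `z_ms` a standard-normal latent factor shared by a
#' module's members and active only in the module's cohorts. Survival times
#' for tumor samples are exponential with a planted hazard ratio tied to
#' high expression of a designated hazard gene.
#'
#' @param design a [cohort_design()].
#' @param annotation annotation table as from [generate_annotation()].
#' @param params a [count_sim_params()].
#' @param seed integer seed.
#' @return a list with elements `counts` (a `count_matrix`: integer matrix
#'   genes x samples plus `sample_meta`) and `truth` (a `ground_truth` list
#'   recording planted log2 fold changes, module membership, the true
#'   within-module edge set per cohort, and the hazard gene).
#' @export
generate_counts <- function(design = cohort_design(),
                            annotation,
                            params = count_sim_params(),
                            seed = 1) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(params, "count_sim_params"))
  set.seed(seed)
  genes <- annotation$gene_id
  G <- length(genes)
  if (G == 0) stop_argument("annotation is empty")

  cohorts <- c(rep("tumorA", design$n_tumor_a),
               rep("tumorB", design$n_tumor_b),
               rep("normal", design$n_normal))
  S <- length(cohorts)
  sample_id <- sprintf("%s_%02d", cohorts, ave(seq_len(S), cohorts,
                                               FUN = seq_along))
  gleason <- integer(S)
  gs_pool <- as.integer(rep(names(design$gleason), design$gleason))
  gleason[cohorts == "tumorA"] <- sample(gs_pool)
  gleason[cohorts == "tumorB"] <- sample(gs_pool)
  gleason[cohorts == "normal"] <- 0L

  b <- rnorm(G, params$baseline_log_mean, params$baseline_log_sd)

  # planted DE: log2FC per tumor cohort, 0 for non-DE genes
  n_de <- floor(params$de_fraction * G)
  de_idx <- sample.int(G, n_de)
  lfc_mag <- runif(n_de, params$de_lfc_range[1], params$de_lfc_range[2])
  lfc <- lfc_mag * sample(c(-1, 1), n_de, replace = TRUE)
  shared <- runif(n_de) < params$de_shared_fraction
  lfc_a <- numeric(G); lfc_b <- numeric(G)
  lfc_a[de_idx] <- lfc
  lfc_b[de_idx[shared]] <- lfc[shared]

  # module membership (disjoint across modules, expressed genes only)
  pool <- if (params$modules_from_de) de_idx[shared] else seq_len(G)
  mu_tumor <- exp(b + log(2) * lfc_a)
  expressed <- pool[mu_tumor[pool] >= params$module_min_mu]
  if (length(expressed) >= sum(vapply(params$modules,
                                      function(m) m$size, 1))) {
    pool <- expressed
  }
  modules <- list()
  taken <- integer()
  for (m in seq_along(params$modules)) {
    spec <- params$modules[[m]]
    avail <- setdiff(pool, taken)
    if (length(avail) < spec$size) {
      stop_argument("not enough genes to form module ", m,
                    " (need ", spec$size, ", have ", length(avail), ")")
    }
    members <- sample(avail, spec$size)
    taken <- c(taken, members)
    loading <- if (!is.null(spec$loading)) {
      rep_len(spec$loading, spec$size)
    } else {
      # calibrate per-gene loading so within-module log-scale correlation
      # sits near target_r. The latent factor inflates the effective NB
      # noise (E[1/(mu e^{wz})] = e^{w^2/2}/mu), so solve the fixed point
      # w^2 = r/(1-r) * (phi + e^{w^2/2}/mu), capped for very low means.
      tr <- spec$target_r %||% 0.8
      mu_g <- exp(b[members] + log(2) * lfc_a[members])
      vapply(mu_g, function(mu) {
        w2 <- tr / (1 - tr) * (params$dispersion + 1 / mu)
        for (k in 1:20) {
          w2 <- min(9, tr / (1 - tr) *
                      (params$dispersion + exp(w2 / 2) / mu))
        }
        sqrt(w2)
      }, 1)
    }
    modules[[m]] <- list(members = genes[members],
                         loading = loading,
                         cohorts = spec$cohorts)
  }

  # latent factors: z_ms active only in the module's cohorts
  eta <- matrix(0, G, S)
  for (mod in modules) {
    z <- numeric(S)
    act <- cohorts %in% mod$cohorts
    z[act] <- rnorm(sum(act))
    midx <- match(mod$members, genes)
    eta[midx, ] <- eta[midx, ] + mod$loading * rep(z, each = length(midx))
  }

  L <- exp(runif(S, log(params$lib_size_range[1]),
                 log(params$lib_size_range[2])))
  d_cohort <- rbind(tumorA = lfc_a, tumorB = lfc_b,
                    normal = numeric(G))
  mu <- matrix(0, G, S)
  for (s in seq_len(S)) {
    mu[, s] <- L[s] * exp(b + log(2) * d_cohort[cohorts[s], ] + eta[, s])
  }
  phi <- params$dispersion
  counts <- if (phi > 0) {
    matrix(rnbinom(G * S, mu = mu, size = 1 / phi), G, S)
  } else {
    matrix(rpois(G * S, lambda = mu), G, S)
  }
  dimnames(counts) <- list(genes, sample_id)

  meta <- data.frame(sample_id = sample_id, cohort = cohorts,
                     gleason = gleason, time = NA_real_, event = NA_integer_,
                     stringsAsFactors = FALSE)

  # planted survival effect for tumor samples, tied to the hazard gene
  hazard <- NULL
  if (!is.null(params$hazard_hr) && n_de > 0) {
    hz_idx <- de_idx[which(lfc > 0 & shared)[1]]
    if (!is.na(hz_idx)) {
      tum <- cohorts != "normal"
      expr <- log1p(counts[hz_idx, tum] / L[tum])
      grp <- ifelse(expr > median(expr), "high", "low")
      surv <- generate_survival(grp, hr = params$hazard_hr,
                                baseline_hazard = params$baseline_hazard,
                                censor_rate = params$censor_rate,
                                seed = seed + 1L)
      meta$time[tum] <- surv$time
      meta$event[tum] <- surv$event
      hazard <- setNames(params$hazard_hr, genes[hz_idx])
    }
  }

  true_edges <- lapply(c(tumorA = "tumorA", tumorB = "tumorB"), function(cc) {
    do.call(rbind, lapply(modules, function(mod) {
      if (!(cc %in% mod$cohorts) || length(mod$members) < 2) return(NULL)
      cmb <- utils::combn(sort(mod$members), 2)
      data.frame(from = cmb[1, ], to = cmb[2, ], stringsAsFactors = FALSE)
    })) %||% data.frame(from = character(), to = character())
  })

  truth <- structure(list(
    de = data.frame(gene_id = genes, lfc_tumorA = lfc_a, lfc_tumorB = lfc_b,
                    stringsAsFactors = FALSE),
    modules = modules,
    true_edges = true_edges,
    hazard = hazard
  ), class = "ground_truth")

  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Container for counts plus sample metadata
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param sample_meta data.frame with columns `sample_id`, `cohort`
#'   (`tumorA`/`tumorB`/`normal`), `gleason`, and optionally `time`, `event`.
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_argument("counts must be non-negative")
  if (ncol(counts) != nrow(sample_meta)) {
    stop_argument("sample_meta rows must match count columns")
  }
  if (!all(c("sample_id", "cohort") %in% names(sample_meta))) {
    stop_argument("sample_meta needs sample_id and cohort columns")
  }
  if (is.null(colnames(counts))) colnames(counts) <- sample_meta$sample_id
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$sample_meta$cohort)),
                            table(x$sample_meta$cohort)), collapse = ", ")))
  invisible(x)
}

#' Simulate survival outcomes for a planted hazard effect
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hr^[group == "high"]`; censoring is an independent
#' exponential with rate `censor_rate` (0 means no censoring).
#'
#' @param group per-sample label, `"high"`/`"low"` (or logical, TRUE = high).
#' @param hr hazard ratio of the high group; must be positive.
#' @param baseline_hazard baseline event rate per unit time.
#' @param censor_rate censoring rate per unit time.
#' @param seed integer seed.
#' @return data.frame with columns `time` and `event` (1 = observed).
#' @export
generate_survival <- function(group, hr, baseline_hazard = 1e-3,
                              censor_rate = 5e-4, seed = 1) {
  if (!is.numeric(hr) || length(hr) != 1 || hr <= 0) {
    stop_argument("hr must be a positive scalar")
  }
  if (is.logical(group)) group <- ifelse(group, "high", "low")
  set.seed(seed)
  n <- length(group)
  rate <- baseline_hazard * ifelse(group == "high", hr, 1)
  t_event <- rexp(n, rate)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Load a packaged table fixture
#'
#' Fixtures mirror published summary tables used in the package's tests:
#' `"table2"` (cohort-A vs cohort-B differentially expressed mRNAs and
#' lncRNAs), `"table3"` (lncRNA--mRNA coexpressed pairs from the
#' cohort-difference network, with upregulation flags), `"venn_counts"`
#' (per-category DE set sizes and overlaps between the two tumor cohorts),
#' and `"table3_coords_synthetic"` (synthetic genomic coordinates for the
#' table3 genes encoding the two known antisense overlaps; the coordinates
#' are constructed, not measured).
#'
#' @param name one of `"table2"`, `"table3"`, `"venn_counts"`,
#'   `"table3_coords_synthetic"`.
#' @return the fixture as a data.frame.
#' @export
load_fixture <- function(name = c("table2", "table3", "venn_counts",
                                  "table3_coords_synthetic")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop_argument("unknown fixture: ",
                                                     name[1]))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "lncoex",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
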