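#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member symbols, tab-separated.
#' Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(list(), description = character()))
  }
  parts <- strsplit(lines, "\t")
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop_argument("GMT line ", short[1], " has fewer than 3 fields")
  }
  nm <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(x) x[-(1:2)])
  dup <- vapply(sets, anyDuplicated, 0L) > 0
  if (any(dup)) {
    warning("duplicate members removed in set(s): ",
            paste(nm[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  structure(setNames(sets, nm), description = setNames(desc, nm))
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set descriptions (default the set name).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query in the
#' universe with the upper-tail hypergeometric probability
#' `P(X >= k)` (population N = universe size, K = set size within the
#' universe, n = query size, k = overlap). Sets are intersected with the
#' universe before testing. A set is called enriched at raw `p < alpha`
#' (no multiple-testing correction by default, matching the conventional
#' pathway-screen usage; pass `adjust = TRUE` for BH).
#'
#' @param query character vector of gene ids/symbols; must lie in
#'   `universe`.
#' @param universe background gene ids/symbols.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha enrichment call threshold on raw p (default 0.05).
#' @param adjust add a BH-adjusted column and call enrichment on it
#'   instead (default FALSE).
#' @return data.frame sorted by p: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `enriched` (and `fdr` when `adjust`).
#' @export
hypergeometric_enrichment <- function(query, universe, sets, alpha = 0.05,
                                      adjust = FALSE) {
  query <- unique(query)
  universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out)) {
    stop_argument("query genes outside the universe: ",
                  paste(head(out, 10), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(query, s))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric())
  }
  res <- res[order(res$p, res$set), , drop = FALSE]
  if (adjust) {
    res$fdr <- bh_fdr(res$p)
    res$enriched <- res$fdr < alpha
  } else {
    res$enriched <- res$p < alpha
  }
  rownames(res) <- NULL
  res
}

#' Split samples at the median expression
#'
#' `"high"` iff the value exceeds the median; values equal to the median
#' go to `"low"` (deterministic tie rule).
#'
#' @param expression per-sample numeric vector (>= 4 samples).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(expression) {
  if (length(expression) < 4) stop_argument("need at least 4 samples")
  if (length(unique(expression)) == 1) {
    stop_argument("all expression values identical; no median split possible")
  }
  m <- median(expression)
  factor(ifelse(expression > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan--Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators (0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `survival`, one row per
#'   distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop_argument("times must be non-negative")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param group two-level grouping.
#' @return list with `chi_square` and `p` (1 df).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop_argument("log-rank needs two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox hazard ratio for a two-group split
#'
#' Proportional-hazards fit of group (high vs low) on the partial
#' likelihood with Breslow tie handling. Non-convergence or complete
#' separation (monotone likelihood) is flagged, not an error.
#'
#' @inheritParams logrank_test
#' @return list: `hr` (high vs low), `coef`, `se`, `p_wald`, `flagged`.
#' @export
cox_hr <- function(time, event, group) {
  group <- as.factor(group)
  # with high/low labels the low group is the reference, so hr is
  # high-vs-low regardless of alphabetical order
  if (setequal(levels(group), c("low", "high"))) {
    group <- factor(group, levels = c("low", "high"))
  }
  if (nlevels(droplevels(group)) < 2) {
    stop_argument("Cox fit needs two non-empty groups")
  }
  if (any(tapply(event, group, sum) == 0)) {
    stop_argument("each group needs at least one event")
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ group, ties = "breslow",
      control = survival::coxph.control(eps = 1e-9, iter.max = 50)
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(hr = NA_real_, coef = NA_real_, se = NA_real_,
                p_wald = NA_real_, flagged = TRUE))
  }
  b <- unname(coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  flagged <- !is.finite(b) || !is.finite(se) || abs(b) > 15 ||
    isFALSE(fit$info$converged %||% TRUE)
  list(hr = exp(b), coef = b, se = se,
       p_wald = 2 * stats::pnorm(-abs(b / se)), flagged = flagged)
}

#' Median-split survival analysis for one gene
#'
#' Splits samples at the gene's median expression, then reports the Cox
#' hazard ratio (high vs low), the log-rank p-value, group sizes, and the
#' per-group Kaplan--Meier curves.
#'
#' @param expression per-sample expression (e.g. a log-CPM row).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return list: `hr`, `p_logrank`, `n_high`, `n_low`, `km_curves`
#'   (data.frame with a `group` column), `cox` (full [cox_hr()] result).
#' @export
survival_analysis <- function(expression, time, event) {
  grp <- median_split(expression)
  lr <- logrank_test(time, event, grp)
  cx <- cox_hr(time, event, grp)
  km <- do.call(rbind, lapply(levels(grp), function(g) {
    cbind(km_estimate(time[grp == g], event[grp == g]), group = g)
  }))
  list(hr = cx$hr, p_logrank = lr$p,
       n_high = sum(grp == "high"), n_low = sum(grp == "low"),
       km_curves = km, cox = cx)
}
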