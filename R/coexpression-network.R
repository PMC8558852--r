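#' Pearson similarity matrix over genes
#'
#' Pairwise Pearson correlation of the rows of an expression matrix
#' (typically log-CPM restricted to one cohort's samples). Genes with zero
#' variance get r = 0 against every other gene (unit diagonal) and are
#' recorded in the `"zero_variance"` attribute.
#'
#' @param x numeric matrix, genes x samples; at least 3 samples.
#' @return symmetric correlation matrix with gene ids as dimnames.
#' @export
pearson_similarity <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop_argument("need at least 3 samples for correlation")
  v <- apply(x, 1, var)
  r <- suppressWarnings(cor(t(x)))
  zv <- rownames(x)[v == 0]
  if (length(zv)) {
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  diag(r) <- 1
  attr(r, "zero_variance") <- zv
  r
}

#' Average local clustering coefficient
#'
#' Watts--Strogatz clustering: per node, `C_i = 2 e_i / (k_i (k_i - 1))`
#' where `e_i` counts edges among the node's neighbours; `C_i = 0` for
#' degree < 2. Returns the mean over non-isolated nodes (0 for an edgeless
#' graph).
#'
#' @param adjacency binary symmetric matrix with zero diagonal.
#' @export
clustering_coefficient <- function(adjacency) {
  a <- as.matrix(adjacency) != 0
  storage.mode(a) <- "numeric"
  if (!isSymmetric(unname(a))) stop_argument("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop_argument("self-loops are not allowed")
  k <- rowSums(a)
  if (all(k == 0)) return(0)
  tri <- diag(a %*% a %*% a) / 2
  ci <- numeric(length(k))
  ok <- k >= 2
  ci[ok] <- 2 * tri[ok] / (k[ok] * (k[ok] - 1))
  mean(ci[k > 0])
}

#' Expected clustering coefficient of an equally dense random graph
#'
#' For an Erdos--Renyi graph the expected clustering coefficient equals the
#' edge density `2 E / (n (n - 1))`.
#'
#' @param n_nodes node count (>= 2).
#' @param n_edges edge count.
#' @export
random_expectation_cr <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop_argument("n_nodes must be >= 2")
  max_e <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_e) stop_argument("n_edges exceeds the maximum possible")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Scale-free fit of a degree sequence
#'
#' Least-squares line of log10 frequency density against log10 degree over
#' logarithmically binned (powers of 2) positive degrees. With fewer than 3
#' occupied bins the fit is meaningless: slope NA and R^2 = 0 with a
#' warning.
#'
#' @param degrees integer degree sequence (isolated nodes may be included;
#'   only positive degrees enter the fit).
#' @return list with `slope` and `r2`.
#' @export
scale_free_fit <- function(degrees) {
  d <- degrees[degrees > 0]
  if (length(d) == 0) stop_argument("all degrees are zero")
  breaks <- 2^(0:max(1, ceiling(log2(max(d) + 1))))
  bin <- findInterval(d, breaks)  # bin i: [2^(i-1), 2^i)
  cnt <- tabulate(bin, nbins = length(breaks) - 1)
  width <- diff(breaks)
  center <- sqrt(breaks[-length(breaks)] * (breaks[-1] - 1))
  keep <- cnt > 0
  if (sum(keep) < 3) {
    warning("fewer than 3 occupied degree bins; scale-free fit undefined")
    return(list(slope = NA_real_, r2 = 0))
  }
  dens <- cnt[keep] / (width[keep] * length(d))
  fit <- lm(log10(dens) ~ log10(center[keep]))
  list(slope = unname(coef(fit)[2]),
       r2 = summary(fit)$r.squared)
}

#' Scan hard thresholds over a similarity matrix
#'
#' For each candidate threshold tau, forms the binary adjacency
#' `|r| >= tau` (off-diagonal) and records the edge count, the observed
#' clustering coefficient Co (over non-isolated nodes), the random-graph
#' expectation Cr at the same density among non-isolated nodes, their
#' difference delta, the scale-free fit R^2 of the positive degree
#' sequence, and the non-isolated node count.
#'
#' @param sim similarity matrix from [pearson_similarity()].
#' @param tau_grid ascending thresholds in (0, 1); default 0.50--0.99 by
#'   0.01.
#' @return a `threshold_scan` data.frame.
#' @export
threshold_scan <- function(sim, tau_grid = seq(0.50, 0.99, by = 0.01)) {
  if (length(tau_grid) == 0) stop_argument("tau_grid is empty")
  if (any(tau_grid <= 0 | tau_grid >= 1)) {
    stop_argument("tau_grid values must lie in (0, 1)")
  }
  if (is.unsorted(tau_grid, strictly = TRUE)) {
    stop_argument("tau_grid must be strictly ascending")
  }
  r <- abs(as.matrix(sim))
  diag(r) <- 0
  rows <- lapply(tau_grid, function(tau) {
    a <- (r >= tau) * 1
    k <- rowSums(a)
    n_edges <- sum(a) / 2
    n_ni <- sum(k > 0)
    co <- clustering_coefficient(a)
    cr <- if (n_ni >= 2) random_expectation_cr(n_ni, n_edges) else 0
    sf <- if (n_ni > 0) {
      suppressWarnings(scale_free_fit(k))
    } else {
      list(slope = NA_real_, r2 = 0)
    }
    data.frame(tau = tau, n_edges = n_edges, co = co, cr = cr,
               delta = co - cr, sf_r2 = sf$r2, sf_slope = sf$slope,
               n_nonisolated = n_ni)
  })
  scan <- do.call(rbind, rows)
  class(scan) <- c("threshold_scan", "data.frame")
  scan
}

#' Select the hard threshold from a scan
#'
#' Among thresholds whose graph passes the scale-free gate
#' (`sf_r2 >= min_sf_r2`) and has at least one edge, returns the tau
#' maximizing `delta = Co - Cr` (observed minus random clustering); ties go
#' to the smallest tau. If no threshold passes the gate, falls back to the
#' overall delta maximum with a warning and marks the result with
#' `attr(, "sf_ok") = FALSE`.
#'
#' @param scan a [threshold_scan()] result.
#' @param min_sf_r2 scale-free gate on the degree-distribution fit R^2
#'   (default 0.8).
#' @param min_nodes minimum non-isolated node count for the scale-free
#'   fit to count as evidence (default 30): a binned log--log regression
#'   on a handful of nodes fits almost anything, so smaller graphs are
#'   treated as having an undefined fit and selection falls back to the
#'   delta maximum.
#' @export
select_threshold <- function(scan, min_sf_r2 = 0.8, min_nodes = 30) {
  if (nrow(scan) == 0) stop_argument("scan is empty")
  withedges <- scan[scan$n_edges > 0, , drop = FALSE]
  if (nrow(withedges) == 0) stop_argument("all rows edgeless")
  gated <- withedges[withedges$sf_r2 >= min_sf_r2 &
                       withedges$n_nonisolated >= min_nodes, , drop = FALSE]
  sf_ok <- nrow(gated) > 0
  if (!sf_ok) {
    warning("no threshold meets the scale-free gate; ",
            "falling back to the overall delta maximum")
    gated <- withedges
  }
  best <- gated$tau[which.max(gated$delta)]  # which.max takes the first tie
  structure(best, sf_ok = sf_ok)
}

#' Build a hard-threshold coexpression network
#'
#' Edge iff `|r| >= tau`; nodes are the non-isolated endpoints, labelled by
#' biotype; each edge carries the correlation and its sign.
#'
#' @param sim similarity matrix.
#' @param tau threshold in (0, 1).
#' @param annotation annotation table supplying `biotype`.
#' @return a `coex_network`: list with `nodes` (data.frame `gene_id`,
#'   `biotype`), `edges` (data.frame `from`, `to`, `r`, `sign`; pairs
#'   ordered `from < to`), and `tau`.
#' @export
build_network <- function(sim, tau, annotation) {
  if (tau <= 0 || tau >= 1) stop_argument("tau must lie in (0, 1)")
  r <- as.matrix(sim)
  ids <- rownames(r)
  a <- abs(r) >= tau
  diag(a) <- FALSE
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  from <- ids[idx[, 1]]
  to <- ids[idx[, 2]]
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  rv <- r[idx]
  edges <- data.frame(from = from, to = to, r = rv,
                      sign = ifelse(rv >= 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$from, edges$to)))
  bt <- annotation$biotype[match(node_ids, annotation$gene_id)]
  if (anyNA(bt)) {
    stop_argument("nodes without biotype: ",
                  paste(head(node_ids[is.na(bt)], 10), collapse = ", "))
  }
  coex_network(data.frame(gene_id = node_ids, biotype = bt,
                          stringsAsFactors = FALSE),
               edges, tau = tau)
}

#' Construct a coexpression network object
#'
#' @param nodes data.frame with `gene_id` and `biotype`.
#' @param edges data.frame with `from`, `to` (and optionally `r`, `sign`);
#'   endpoints must be nodes, no self-loops.
#' @param tau the threshold used, if any.
#' @export
coex_network <- function(nodes, edges, tau = NA_real_) {
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop_argument("self-loops not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes$gene_id)) {
      stop_argument("edge endpoints must be listed in nodes")
    }
  }
  if (is.null(edges$r)) edges$r <- rep(NA_real_, nrow(edges))
  if (is.null(edges$sign)) edges$sign <- rep(NA_integer_, nrow(edges))
  structure(list(nodes = nodes, edges = edges, tau = tau),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("coex_network: %d nodes (%d lncRNA, %d mRNA), %d edges, tau=%s\n",
              nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
              sum(x$nodes$biotype == "mRNA"), nrow(x$edges),
              format(x$tau)))
  invisible(x)
}
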