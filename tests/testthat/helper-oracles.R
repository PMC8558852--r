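# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# average local clustering by explicit triangle enumeration, O(n^3)
bf_clustering <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    if (length(nb) < 2) next
    e <- 0
    for (u in seq_along(nb)) {
      for (v in seq_len(u - 1)) {
        if (a[nb[u], nb[v]] != 0) e <- e + 1
      }
    }
    ci[i] <- 2 * e / (length(nb) * (length(nb) - 1))
  }
  if (all(k == 0)) 0 else mean(ci[k > 0])
}

# connected components via union-find over an edge list
bf_components <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_along(from)) {
    ri <- find(match(from[e], nodes))
    rj <- find(match(to[e], nodes))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, 1L)
  as.integer(table(roots))
}

# BH adjusted p by the definition: min over j >= rank(i) of m * p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  adj
}

# TMM factor for one sample against a reference column, by the formula
bf_tmm_factor <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  no <- sum(obs); nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / no) / (r / nr))
  a <- (log2(o / no) + log2(r / nr)) / 2
  w <- (no - o) / (no * o) + (nr - r) / (nr * r)
  fin <- is.finite(m) & is.finite(a) & abs(a) < 1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  lm_ <- quantile(m, c(trim_m, 1 - trim_m), type = 7)
  la_ <- quantile(a, c(trim_a, 1 - trim_a), type = 7)
  keep2 <- m >= lm_[1] & m <= lm_[2] & a >= la_[1] & a <= la_[2]
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# upper-tail hypergeometric by exact combinatorial enumeration
bf_hyper_upper <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Breslow log partial likelihood for a single binary covariate
bf_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# log-rank statistic assembled from first principles
bf_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1)
    n0 <- sum(at_risk & g == 0)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    n <- n1 + n0
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# random symmetric 0/1 adjacency with no self-loops
random_adjacency <- function(n, p = 0.2) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# random coex_network over a gene universe
random_network <- function(genes, p = 0.15) {
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pmin(pairs[keep, 1], pairs[keep, 2]),
                      to = pmax(pairs[keep, 1], pairs[keep, 2]),
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$from, edges$to)))
  coex_network(data.frame(gene_id = ids,
                          biotype = rep("mRNA", length(ids))),
               edges)
}
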