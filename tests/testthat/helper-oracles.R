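# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force double sums, exhaustive enumeration,
# closed-form tail sums, hand-rolled step-up adjustment.

# Benjamini-Hochberg by the literal step-up definition:
# p_adj(i) = min_{j: p_(j) >= p_(i) in rank} p_(j) * m / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    tail_vals <- vapply(i:m, function(j) sorted[j] * m / j, numeric(1))
    adj[ord[i]] <- min(1, min(tail_vals))
  }
  adj
}

# Weighted Newman-Girvan modularity by the literal double sum over all
# ordered node pairs.
oracle_modularity <- function(edges, membership, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  nodes <- names(membership)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    a <- edges$protein_a[e]; b <- edges$protein_b[e]
    W[a, b] <- W[a, b] + weights[e]
    W[b, a] <- W[b, a] + weights[e]
  }
  s <- rowSums(W)
  m2 <- sum(s)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[[nodes[i]]] == membership[[nodes[j]]])
      q <- q + W[i, j] - s[i] * s[j] / m2
  }
  unname(q / m2)
}

# All set partitions of 1..n as restricted-growth label vectors.
set_partitions <- function(n) {
  out <- list()
  recur <- function(labels, mx) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) recur(c(labels, v), max(mx, v))
  }
  recur(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search on a small graph (n <= ~9).
oracle_best_q <- function(edges, nodes, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    W[edges$protein_a[e], edges$protein_b[e]] <-
      W[edges$protein_a[e], edges$protein_b[e]] + weights[e]
    W[edges$protein_b[e], edges$protein_a[e]] <-
      W[edges$protein_b[e], edges$protein_a[e]] + weights[e]
  }
  s <- rowSums(W)
  m2 <- sum(s)
  B <- W - outer(s, s) / m2
  best <- -Inf
  for (lab in set_partitions(n)) {
    same <- outer(lab, lab, "==")
    q <- sum(B[same]) / m2
    if (q > best) best <- q
  }
  best
}

# One-sided hypergeometric upper tail P(X >= k) by the closed-form sum of
# binomial coefficients.
oracle_hyper_tail <- function(k, N, K, n) {
  if (K == 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random simple weighted graph on n nodes.
random_graph <- function(n, p = 0.4, weighted = TRUE) {
  cb <- t(combn(n, 2))
  keep <- runif(nrow(cb)) < p
  if (!any(keep)) keep[sample(nrow(cb), 1)] <- TRUE
  data.frame(protein_a = paste0("n", cb[keep, 1]),
             protein_b = paste0("n", cb[keep, 2]),
             weight = if (weighted) runif(sum(keep), 0.2, 2) else
               rep(1, sum(keep)),
             stringsAsFactors = FALSE)
}

# Stability-score recount by a plain double loop over edges and regions.
oracle_stability <- function(memberships, edges) {
  score <- integer(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    for (m in memberships) {
      if (m[[edges$protein_a[e]]] != m[[edges$protein_b[e]]])
        score[e] <- score[e] + 1L
    }
  }
  score
}

# Small tensor built by hand from a protein x (region x replicate) layout.
make_tensor <- function(values, regions, replicates, peptides = NULL) {
  P <- nrow(values)
  proteins <- rownames(values) %||% paste0("P", seq_len(P))
  arr <- array(NA_real_, c(P, length(regions), length(replicates)),
               dimnames = list(proteins, regions, paste0("B", replicates)))
  j <- 0
  for (r in seq_along(regions)) for (k in seq_along(replicates)) {
    j <- j + 1
    arr[, r, k] <- values[, j]
  }
  if (is.null(peptides)) peptides <- setNames(rep(3L, P), proteins)
  new_abundance_tensor(arr, peptides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
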