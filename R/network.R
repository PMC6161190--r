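# Abundance-weighted PPI networks and community detection by recursive
# spectral modularity maximization (leading eigenvector of the generalized
# modularity matrix) with a Kernighan-Lin style fine-tuning pass after every
# bipartition. Entirely deterministic: eigenvectors come from a fixed-start
# shifted power iteration (LAPACK eigen for small blocks), sign ties go to
# group 1, and fine-tuning breaks ties on the lowest node index.

#' Build the quantified-protein PPI graph
#'
#' Keeps edges whose two endpoints are both quantified, drops self-loops and
#' duplicate (undirected) edges.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`.
#' @param quantified character vector of quantified protein ids.
#' @return A list of class `psd_network`: `nodes`, `edges` (deduplicated,
#'   endpoints ordered), and `dropped` (counts of removed self-loops,
#'   unquantified-endpoint edges and duplicates).
#' @export
build_network <- function(edges, quantified) {
  stopifnot(is.data.frame(edges), all(c("protein_a", "protein_b") %in%
                                        names(edges)))
  a <- as.character(edges$protein_a); b <- as.character(edges$protein_b)
  n0 <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  keep <- a %in% quantified & b %in% quantified
  n_unq <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  ed <- data.frame(protein_a = lo[!dup], protein_b = hi[!dup],
                   stringsAsFactors = FALSE)
  if (nrow(ed) == 0)
    stopf("no PPI edges remain after filtering to quantified proteins")
  nodes <- sort(unique(c(ed$protein_a, ed$protein_b)))
  structure(list(nodes = nodes, edges = ed,
                 dropped = c(self_loops = sum(self),
                             unquantified = n_unq, duplicates = sum(dup))),
            class = "psd_network")
}

#' @export
print.psd_network <- function(x, ...) {
  cat(sprintf("psd_network: %d nodes, %d edges (dropped: %s)\n",
              length(x$nodes), nrow(x$edges),
              paste(names(x$dropped), x$dropped, collapse = ", ")))
  invisible(x)
}

#' Weight network edges per region by mean endpoint abundance
#'
#' The weight of interaction (a, b) in region r is
#' `w_r(a, b) = (Exp_r(a) + Exp_r(b)) / 2`, the mean of the two endpoints'
#' mean abundances in that region; topology is shared across regions.
#'
#' @param network a `psd_network`.
#' @param mean_abund protein x region matrix of mean abundances covering all
#'   network nodes.
#' @return A list of class `psd_regional_graphs`: `nodes`, `edges`, `weights`
#'   (edge x region matrix).
#' @export
weight_edges <- function(network, mean_abund) {
  stopifnot(inherits(network, "psd_network"))
  miss <- setdiff(network$nodes, rownames(mean_abund))
  if (length(miss))
    stopf("no abundance for protein '%s' (any region)", miss[1])
  ia <- match(network$edges$protein_a, rownames(mean_abund))
  ib <- match(network$edges$protein_b, rownames(mean_abund))
  w <- (mean_abund[ia, , drop = FALSE] + mean_abund[ib, , drop = FALSE]) / 2
  rownames(w) <- NULL
  if (any(!is.finite(w)))
    stopf("missing abundance when weighting edges")
  structure(list(nodes = network$nodes, edges = network$edges, weights = w),
            class = "psd_regional_graphs")
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * delta(c_i, c_j)` with `s` the
#' weighted degrees (strengths) and `m` the total edge weight.
#'
#' @param edges data.frame `protein_a`, `protein_b`.
#' @param weights numeric edge weights (default 1).
#' @param membership named community id per node (must cover all endpoints).
#' @return Modularity Q.
#' @export
modularity_q <- function(edges, membership, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  nodes <- names(membership)
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  if (anyNA(ia) || anyNA(ib)) stopf("membership must cover all edge endpoints")
  m <- sum(weights)
  if (m <= 0) stopf("total edge weight is zero")
  s <- numeric(length(nodes))
  for (e in seq_along(weights)) {
    s[ia[e]] <- s[ia[e]] + weights[e]
    s[ib[e]] <- s[ib[e]] + weights[e]
  }
  comm <- as.integer(factor(membership))
  # per-community sums of intra-edge weight and of strengths
  intra <- numeric(max(comm))
  same <- comm[ia] == comm[ib]
  if (any(same)) {
    agg <- tapply(weights[same], comm[ia][same], sum)
    intra[as.integer(names(agg))] <- agg
  }
  s_c <- tapply(s, comm, sum)
  sum(intra / m) - sum((s_c / (2 * m))^2)
}

# Dense generalized modularity matrix for a node subset g (indices into the
# full graph), following Newman: B^(g)_ij = B_ij - delta_ij sum_{k in g} B_ik.
modularity_block <- function(adj, s, m2, g) {
  Wgg <- adj[g, g, drop = FALSE]
  B <- Wgg - outer(s[g], s[g]) / m2
  diag(B) <- diag(B) - (rowSums(Wgg) - s[g] * sum(s[g]) / m2)
  B
}

# Leading eigenpair of a symmetric matrix. Small blocks use LAPACK; larger
# blocks a shifted power iteration with a deterministic start vector
# (all-ones plus an index-based perturbation). Falls back to LAPACK if the
# iteration has not converged (near-degenerate leading pair).
leading_eigen <- function(B, tol = 1e-10, maxit = 2000L, dense_cut = 64L) {
  n <- nrow(B)
  if (n <= dense_cut) {
    e <- eigen(B, symmetric = TRUE)
    return(list(value = e$values[1], vector = e$vectors[, 1]))
  }
  shift <- max(rowSums(abs(B)))
  v <- 1 + 1e-3 * seq_len(n) / n
  v <- v / sqrt(sum(v^2))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    u <- as.vector(B %*% v) + shift * v
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    if (max(abs(u - v)) < tol || max(abs(u + v)) < tol) {
      v <- u
      converged <- TRUE
      break
    }
    v <- u
  }
  if (!converged) {
    e <- eigen(B, symmetric = TRUE)
    return(list(value = e$values[1], vector = e$vectors[, 1]))
  }
  list(value = sum(v * as.vector(B %*% v)), vector = v)
}

# Kernighan-Lin style fine-tuning of a bipartition sign vector s for the
# block matrix B (maximizes s' B s). Each pass moves every node at most once,
# always taking the single move with the largest gain (ties -> lowest index),
# and keeps the best intermediate state; passes repeat while they improve by
# more than tol (which the caller scales to the weight magnitude, so
# floating-point noise never counts as improvement).
kl_refine <- function(B, s, tol = 1e-12) {
  n <- length(s)
  dB <- diag(B)
  repeat {
    g <- as.vector(B %*% s) - dB * s       # g_i = sum_{k != i} B_ik s_k
    movable <- rep(TRUE, n)
    cum <- 0
    best <- 0
    best_at <- 0L
    order_moved <- integer(n)
    s_pass <- s
    for (step in seq_len(n)) {
      delta <- -4 * s_pass * g
      delta[!movable] <- -Inf
      j <- which.max(delta)
      cum <- cum + delta[j]
      sj <- s_pass[j]
      g <- g - 2 * B[, j] * sj
      g[j] <- g[j] + 2 * B[j, j] * sj
      s_pass[j] <- -sj
      movable[j] <- FALSE
      order_moved[step] <- j
      if (cum > best + tol) {
        best <- cum
        best_at <- step
      }
    }
    if (best <= tol) return(s)
    # keep flips up to the best prefix only
    flip <- order_moved[seq_len(best_at)]
    s[flip] <- -s[flip]
  }
}

#' Partition a weighted graph by recursive spectral modularity maximization
#'
#' Communities are found by recursively bipartitioning on the sign of the
#' leading eigenvector of the (generalized, strength-weighted) modularity
#' matrix, refining every split with a Kernighan-Lin fine-tuning pass, and
#' stopping when a proposed split no longer increases total modularity
#' (indivisible community). Connected components are pre-split and never
#' merged. Fully deterministic.
#'
#' @param edges data.frame `protein_a`, `protein_b` (undirected, simple).
#' @param weights numeric edge weights (> 0); default 1 (unweighted).
#' @param nodes optional node id vector (defaults to the edge endpoints;
#'   isolated extra nodes become singleton communities).
#' @return A list of class `psd_partition`: `membership` (named community id
#'   per node, contiguous from 1), `Q`, `n_communities`.
#' @export
spectral_partition <- function(edges, weights = NULL, nodes = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (any(weights <= 0)) stopf("edge weights must be > 0")
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  if (n == 0) stopf("empty graph")
  membership <- setNames(rep(NA_integer_, n), nodes)
  if (nrow(edges) == 0) {
    membership[] <- seq_len(n)
    return(structure(list(membership = membership, Q = NA_real_,
                          n_communities = n), class = "psd_partition"))
  }
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  # modularity is invariant to weight scale: normalize so tolerances are
  # meaningful for any abundance magnitude
  wn <- weights / mean(weights)
  adj <- matrix(0, n, n)
  for (e in seq_along(wn)) {
    adj[ia[e], ib[e]] <- adj[ia[e], ib[e]] + wn[e]
    adj[ib[e], ia[e]] <- adj[ib[e], ia[e]] + wn[e]
  }
  s <- rowSums(adj)
  m2 <- sum(s)                      # 2m
  eps <- 1e-10 * m2
  next_id <- 0L
  assign_comm <- function(g) {
    next_id <<- next_id + 1L
    membership[g] <<- next_id
  }
  split_group <- function(g) {
    if (length(g) == 1) return(assign_comm(g))
    B <- modularity_block(adj, s, m2, g)
    le <- leading_eigen(B)
    if (le$value <= eps) return(assign_comm(g))
    sv <- ifelse(le$vector > 0, 1, -1)   # ties (exact zeros) -> group 1
    sv <- kl_refine(B, sv, tol = eps)
    dq <- sum(sv * as.vector(B %*% sv))  # = 4m * deltaQ
    if (dq <= eps || length(unique(sv)) == 1) return(assign_comm(g))
    split_group(g[sv > 0])
    split_group(g[sv < 0])
  }
  comp <- igraph::components(igraph::graph_from_edgelist(
    cbind(ia, ib), directed = FALSE))$membership
  # vertices beyond max(ia, ib) (isolated) are absent; handle them as singletons
  comp <- comp[seq_len(min(length(comp), n))]
  for (cc in sort(unique(comp))) split_group(which(comp == cc))
  if (anyNA(membership)) {
    for (i in which(is.na(membership))) assign_comm(i)
  }
  # relabel contiguously in order of first appearance
  membership <- setNames(as.integer(factor(membership,
                                           levels = unique(membership))),
                         nodes)
  Q <- modularity_q(edges, membership, weights)
  structure(list(membership = membership, Q = Q,
                 n_communities = max(membership)),
            class = "psd_partition")
}

#' @export
print.psd_partition <- function(x, ...) {
  cat(sprintf("psd_partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  invisible(x)
}

#' Cluster every regional weighted graph
#'
#' Runs [spectral_partition()] once per region with that region's edge
#' weights.
#'
#' @param rg a `psd_regional_graphs` from [weight_edges()].
#' @return A list of class `psd_regional_partitions`: `partitions` (named list
#'   of `psd_partition`), `summary` (data.frame region, n_communities, Q).
#' @export
cluster_all_regions <- function(rg) {
  stopifnot(inherits(rg, "psd_regional_graphs"))
  regions <- colnames(rg$weights)
  parts <- lapply(regions, function(r)
    spectral_partition(rg$edges, rg$weights[, r], nodes = rg$nodes))
  names(parts) <- regions
  structure(list(
    partitions = parts,
    summary = data.frame(region = regions,
                         n_communities = vapply(parts, `[[`, integer(1),
                                                "n_communities"),
                         Q = vapply(parts, `[[`, numeric(1), "Q"),
                         row.names = NULL, stringsAsFactors = FALSE)),
    class = "psd_regional_partitions")
}

#' @export
print.psd_regional_partitions <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
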