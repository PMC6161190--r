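# Stable core network: per-edge cluster co-membership stability across
# regional partitions, stable-edge selection, and overlap of stable clusters
# with proteome modules.

#' Score every interaction's cluster co-membership stability across regions
#'
#' An edge scores 1 in a region where its endpoints land in different
#' communities and 0 where they are co-clustered; scores are summed over
#' regions, so 0 means always co-clustered and R (the number of regions)
#' means never. No label alignment across regions is needed: only
#' within-region co-membership enters.
#'
#' @param partitions a `psd_regional_partitions` (or named list of
#'   `psd_partition` / membership vectors).
#' @param edges data.frame `protein_a`, `protein_b`.
#' @return data.frame `protein_a`, `protein_b`, `score`, plus one logical
#'   `split_<region>` column per region.
#' @export
stability_scores <- function(partitions, edges) {
  if (inherits(partitions, "psd_regional_partitions"))
    partitions <- partitions$partitions
  memb <- lapply(partitions, function(p)
    if (inherits(p, "psd_partition")) p$membership else p)
  out <- edges[c("protein_a", "protein_b")]
  score <- integer(nrow(edges))
  for (r in names(memb)) {
    ma <- memb[[r]][edges$protein_a]
    mb <- memb[[r]][edges$protein_b]
    if (anyNA(ma) || anyNA(mb))
      stopf("region '%s': partition does not cover all edge endpoints", r)
    split <- ma != mb
    out[[paste0("split_", r)]] <- unname(split)
    score <- score + split
  }
  out$score <- score
  out[c("protein_a", "protein_b", "score",
        setdiff(names(out), c("protein_a", "protein_b", "score")))]
}

#' Select the stable core network
#'
#' Keeps edges whose stability score is at most `max_score` (default 2: with
#' seven regions, endpoints co-clustered in at least 5/7 of the regional
#' networks) and re-clusters the stable graph with [spectral_partition()].
#'
#' @param scores data.frame from [stability_scores()].
#' @param max_score maximum stability score retained.
#' @param weights optional per-edge weights (aligned with `scores` rows) used
#'   when re-clustering; by convention the across-region mean abundance
#'   weight.
#' @param recluster logical; cluster the stable graph (default TRUE).
#' @return A list of class `psd_stable`: `edges` (stable subset incl. score),
#'   `n_total`, `n_stable`, `fraction`, `partition` (or NULL).
#' @export
select_stable <- function(scores, max_score = 2, weights = NULL,
                          recluster = TRUE) {
  keep <- scores$score <= max_score
  ed <- scores[keep, , drop = FALSE]
  part <- NULL
  if (nrow(ed) == 0) {
    warning("stable edge set is empty", call. = FALSE)
    recluster <- FALSE
  }
  if (recluster)
    part <- spectral_partition(ed, weights = weights[keep])
  structure(list(edges = ed, n_total = nrow(scores), n_stable = nrow(ed),
                 fraction = nrow(ed) / nrow(scores), max_score = max_score,
                 partition = part),
            class = "psd_stable")
}

#' @export
print.psd_stable <- function(x, ...) {
  cat(sprintf("psd_stable: %d / %d edges (%.0f%%) with score <= %d",
              x$n_stable, x$n_total, 100 * x$fraction, x$max_score))
  if (!is.null(x$partition))
    cat(sprintf("; %d clusters, Q = %.3f", x$partition$n_communities,
                x$partition$Q))
  cat("\n")
  invisible(x)
}

#' Overlap of stable-network clusters with proteome modules
#'
#' One-sided hypergeometric test of each (cluster, module) overlap against
#' the shared protein universe, BH-adjusted across all pairs.
#'
#' @param clusters named community id per protein (e.g. the stable
#'   partition's membership).
#' @param modules named module id per protein (e.g. `psd_ppm$labels`).
#' @param universe character vector of protein ids; default the union of the
#'   two label sets' names.
#' @return data.frame `cluster`, `module`, `overlap`, `cluster_size`,
#'   `module_size`, `universe`, `p`, `p_adj`.
#' @export
module_overlap <- function(clusters, modules, universe = NULL) {
  if (is.null(universe))
    universe <- union(names(clusters), names(modules))
  N <- length(universe)
  cl_sets <- split(intersect(names(clusters), universe),
                   clusters[intersect(names(clusters), universe)])
  mod_sets <- split(intersect(names(modules), universe),
                    modules[intersect(names(modules), universe)])
  rows <- list()
  for (ci in names(cl_sets)) for (mi in names(mod_sets)) {
    k <- length(intersect(cl_sets[[ci]], mod_sets[[mi]]))
    n <- length(cl_sets[[ci]]); K <- length(mod_sets[[mi]])
    p <- if (n == 0 || K == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = ci, module = mi, overlap = k, cluster_size = n,
      module_size = K, universe = N, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), ]
}
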