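# Regional signatures: differential stability across individual brains,
# hierarchical clustering of regional profiles, proteome-module (PPM)
# detection by internal cluster-number indices, and Circos link tables.

#' Differential stability (average pairwise Pearson correlation)
#'
#' For each protein, its per-brain regional profile (intensity across regions
#' for one replicate brain) is correlated between every pair of brains and
#' the Pearson coefficients averaged. High values mean the protein's regional
#' pattern reproduces across individuals. A brain with a constant profile
#' makes its pairs undefined: those pairs are skipped, `n_pairs` is reduced
#' and the protein flagged.
#'
#' @param tensor an `abundance_tensor` with >= 2 replicates and >= 3 regions.
#' @return data.frame with `protein_id`, `avg_cor`, `n_pairs`, `flagged`.
#' @export
differential_stability <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  K <- length(tensor$replicates)
  if (K < 2) stopf("differential stability needs >= 2 brains")
  if (length(tensor$regions) < 3) stopf("differential stability needs >= 3 regions")
  x <- tensor$intensities
  res <- lapply(seq_along(tensor$proteins), function(p) {
    m <- x[p, , ]                       # regions x brains
    const <- apply(m, 2, sd) == 0
    cc <- suppressWarnings(cor(m))
    pairs <- cc[upper.tri(cc)]
    ok <- !is.na(pairs)
    data.frame(avg_cor = if (any(ok)) mean(pairs[ok]) else NA_real_,
               n_pairs = sum(ok), flagged = any(const))
  })
  out <- do.call(rbind, res)
  cbind(data.frame(protein_id = tensor$proteins, stringsAsFactors = FALSE),
        out)
}

#' Select the high-stability protein subset
#'
#' @param records data.frame from [differential_stability()].
#' @param cutoff numeric cutoff on `avg_cor`; default the median (structurally
#'   "roughly half" of the proteins).
#' @return Character vector of protein ids with `avg_cor >= cutoff`.
#' @export
select_high_ds <- function(records, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- median(records$avg_cor, na.rm = TRUE)
  records$protein_id[!is.na(records$avg_cor) & records$avg_cor >= cutoff]
}

#' Hierarchical clustering of the protein x region abundance matrix
#'
#' Rows (proteins) are Z-scored, then clustered agglomeratively; regions are
#' clustered on the columns of the same row-scaled matrix. Defaults follow
#' standard heatmap practice: Euclidean distance, complete linkage.
#'
#' @param mat protein x region numeric matrix (typically mean abundances).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param scale_rows Z-score rows first (default TRUE).
#' @return A list of class `psd_hclust`: `row_hclust`, `col_hclust`,
#'   `scaled` (the matrix actually clustered).
#' @export
hierarchical_cluster <- function(mat, metric = "euclidean",
                                 linkage = "complete", scale_rows = TRUE) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  sc <- if (scale_rows) {
    z <- zscore_profile(mat)
    attr(z, "flagged") <- NULL
    z
  } else mat
  row_hc <- if (nrow(sc) > 1)
    hclust(dist(sc, method = metric), method = linkage) else NULL
  col_hc <- if (ncol(sc) > 1)
    hclust(dist(t(sc), method = metric), method = linkage) else NULL
  structure(list(row_hclust = row_hc, col_hclust = col_hc, scaled = sc),
            class = "psd_hclust")
}

# Calinski-Harabasz pseudo-F for a labelled matrix.
ch_index <- function(mat, labels) {
  n <- nrow(mat); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(mat)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    rows <- mat[labels == g, , drop = FALSE]
    cm <- colMeans(rows)
    ssb <- ssb + nrow(rows) * sum((cm - grand)^2)
    ssw <- ssw + sum(sweep(rows, 2, cm)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Dunn index: min between-cluster distance / max within-cluster diameter.
dunn_index <- function(d, labels) {
  dm <- as.matrix(d)
  k <- unique(labels)
  if (length(k) < 2) return(NA_real_)
  sep <- Inf; diam <- 0
  for (i in seq_along(k)) {
    ri <- labels == k[i]
    if (sum(ri) > 1) diam <- max(diam, max(dm[ri, ri]))
    for (j in seq_along(k)) if (j > i)
      sep <- min(sep, min(dm[ri, labels == k[j]]))
  }
  if (diam == 0) return(Inf)
  sep / diam
}

#' Choose the number of clusters by majority vote of internal indices
#'
#' Cuts the protein dendrogram at each `K` in `k_range` and scores the
#' partition with three internal indices: mean silhouette width
#' ([cluster::silhouette()]), Calinski-Harabasz, and Dunn. Each index votes
#' for its best `K`; the majority wins, ties going to the smallest `K`.
#'
#' @param mat protein x region matrix (rows Z-scored internally as in
#'   [hierarchical_cluster()]).
#' @param k_range integer candidate cluster numbers (within `[2, nrow-1]`).
#' @param hc optional precomputed `psd_hclust` for `mat`.
#' @return Integer `K`, with attribute `"scores"` (index value per K) and
#'   `"votes"`.
#' @export
choose_k <- function(mat, k_range = 2:8, hc = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > nrow(mat) - 1))
    stopf("'k_range' must lie within [2, nrow(mat) - 1]")
  if (is.null(hc)) hc <- hierarchical_cluster(mat)
  sc <- hc$scaled
  if (all(dist(sc) == 0)) stopf("degenerate matrix: all rows identical")
  d <- dist(sc)
  scores <- sapply(k_range, function(k) {
    labels <- cutree(hc$row_hclust, k = k)
    sil <- mean(cluster::silhouette(labels, d)[, "sil_width"])
    c(silhouette = sil, ch = ch_index(sc, labels), dunn = dunn_index(d, labels))
  })
  colnames(scores) <- k_range
  best <- apply(scores, 1, function(row) {
    if (all(!is.finite(row))) return(k_range[1])
    k_range[which.max(row)]
  })
  votes <- table(factor(best, levels = k_range))
  K <- as.integer(names(votes)[votes == max(votes)][1])
  structure(K, scores = scores, votes = votes)
}

#' Detect postsynaptic proteome modules (PPMs)
#'
#' Clusters the Z-scored protein x region mean-abundance matrix, selects the
#' module count with [choose_k()] (or uses a fixed `k`), and cuts the
#' dendrogram.
#'
#' @param mat protein x region mean-abundance matrix.
#' @param k fixed module count, or NULL to select via `k_range`.
#' @param k_range candidate counts when `k` is NULL.
#' @return A list of class `psd_ppm`: `labels` (named module id per protein,
#'   1..K), `K`, `hclust` (`psd_hclust`), `chosen` (the [choose_k()] result or
#'   NULL).
#' @export
detect_ppms <- function(mat, k = NULL, k_range = 2:8) {
  hc <- hierarchical_cluster(mat)
  chosen <- NULL
  if (is.null(k)) {
    chosen <- choose_k(mat, k_range, hc = hc)
    k <- as.integer(chosen)
  }
  labels <- cutree(hc$row_hclust, k = k)
  structure(list(labels = labels, K = as.integer(k), hclust = hc,
                 chosen = chosen), class = "psd_ppm")
}

#' @export
print.psd_ppm <- function(x, ...) {
  cat(sprintf("psd_ppm: %d modules over %d proteins\n", x$K,
              length(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Region-presence mask
#'
#' Which regions a protein is counted "positive" in. With
#' `method = "above_mean"` (default) a protein is positive in regions where
#' its mean abundance exceeds its geometric mean across regions; with
#' `method = "threshold"` where abundance exceeds `threshold`.
#'
#' @param mean_abund protein x region mean-abundance matrix.
#' @param method `"above_mean"` or `"threshold"`.
#' @param threshold numeric, for `method = "threshold"`.
#' @return Logical protein x region matrix.
#' @export
region_presence <- function(mean_abund, method = c("above_mean", "threshold"),
                            threshold = 0) {
  method <- match.arg(method)
  if (method == "above_mean") {
    gm <- exp(rowMeans(log(mean_abund)))
    mean_abund > gm
  } else mean_abund > threshold
}

#' Build the Circos link table from modules and region presence
#'
#' Proteins positive in more than one region link those regions. Each such
#' protein contributes one unit to its region's outgoing links, split equally
#' over its `k - 1` partner regions (k = number of positive regions), so that
#' the link widths leaving any region sum to at most 1. Width of a
#' (region_a, region_b, module) link is the summed contribution of that
#' module's proteins positive in both regions, divided by the number of
#' proteins positive in `region_a`.
#'
#' @param labels named module id per protein (e.g. `psd_ppm$labels`).
#' @param presence logical protein x region matrix from [region_presence()].
#' @return data.frame `region_a`, `region_b`, `module`, `width`, `n_proteins`;
#'   unordered pairs appear in both orientations so each region's outgoing
#'   widths are explicit.
#' @export
circos_links <- function(labels, presence) {
  stopifnot(all(rownames(presence) %in% names(labels)))
  labels <- labels[rownames(presence)]
  regions <- colnames(presence)
  kpos <- rowSums(presence)
  multi <- kpos > 1
  out <- list()
  for (a in regions) {
    n_a <- sum(presence[, a])
    if (n_a == 0) next
    for (b in setdiff(regions, a)) {
      both <- multi & presence[, a] & presence[, b]
      if (!any(both)) next
      for (m in sort(unique(labels[both]))) {
        sel <- both & labels == m
        w <- sum(1 / (kpos[sel] - 1)) / n_a
        out[[length(out) + 1L]] <- data.frame(
          region_a = a, region_b = b, module = m, width = w,
          n_proteins = sum(sel), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(region_a = character(), region_b = character(),
                      module = integer(), width = numeric(),
                      n_proteins = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
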