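# Connectome-proteome correlation: regional mean abundance against the mean
# projection-volume (connectivity) vector.

#' Connectivity vector: row-wise mean projection volume
#'
#' For each source region, the mean of its projection volumes to all regions
#' including itself (the diagonal is part of the mean).
#'
#' @param m square region x region non-negative matrix with matching
#'   row/column names.
#' @return Named numeric vector, one mean per region.
#' @export
connectivity_vector <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("connectome matrix must be square")
  rowMeans(m)
}

#' Correlate each protein's regional abundance with connectivity
#'
#' Pearson r across regions between the protein's mean abundance profile and
#' the connectivity vector; also reports r-squared and the Fisher
#' z-transform `atanh(r)` (r clipped at `1 - 1e-12` in magnitude). Proteins
#' with a constant profile have undefined r: they are flagged and never
#' selected.
#'
#' @param mean_abund protein x region mean-abundance matrix (>= 3 regions).
#' @param vector connectivity vector from [connectivity_vector()]; must not
#'   be constant.
#' @param r2_threshold selection threshold on r-squared (default 0.6).
#' @return data.frame `protein_id`, `r`, `r2`, `z`, `selected`, `flagged`.
#' @export
correlate_proteins <- function(mean_abund, vector, r2_threshold = 0.6) {
  if (ncol(mean_abund) < 3) stopf("need >= 3 regions for correlation")
  v <- vector[colnames(mean_abund)]
  if (anyNA(v)) stopf("connectivity vector does not cover all regions")
  if (sd(v) == 0)
    stopf("connectivity vector is constant; correlation undefined")
  flagged <- apply(mean_abund, 1, sd) == 0
  r <- rep(NA_real_, nrow(mean_abund))
  r[!flagged] <- suppressWarnings(
    as.vector(cor(t(mean_abund[!flagged, , drop = FALSE]), v)))
  rc <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  data.frame(protein_id = rownames(mean_abund), r = r, r2 = r^2,
             z = atanh(rc), selected = !flagged & !is.na(r) &
               r^2 >= r2_threshold,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Protein-by-source-region correlation matrix, clustered
#'
#' Correlates every protein's regional abundance profile with each source
#' region's projection-volume row (the per-source connectivity vectors) and
#' hierarchically clusters the resulting protein x region correlation matrix
#' (heatmap-ready; the Fisher z transform of each entry is exported).
#'
#' @param mean_abund protein x region mean-abundance matrix.
#' @param connectome square region x region matrix.
#' @param scale_rows passed to [hierarchical_cluster()] (default FALSE:
#'   correlations are already on a common scale).
#' @return A list of class `psd_conn_cluster`: `cor` (protein x region r),
#'   `z` (Fisher z), `hclust` (a `psd_hclust` on `cor`).
#' @export
correlation_cluster <- function(mean_abund, connectome, scale_rows = FALSE) {
  if (!is.matrix(connectome) || nrow(connectome) != ncol(connectome))
    stopf("connectome matrix must be square")
  regs <- colnames(mean_abund)
  cm <- connectome[regs, regs]
  cc <- matrix(NA_real_, nrow(mean_abund), length(regs),
               dimnames = list(rownames(mean_abund), regs))
  for (srg in regs) {
    v <- cm[srg, ]
    if (sd(v) == 0)
      stopf("constant connectivity for source region '%s'", srg)
    cc[, srg] <- suppressWarnings(as.vector(cor(t(mean_abund), v)))
  }
  keep <- !apply(cc, 1, anyNA)
  hc <- hierarchical_cluster(cc[keep, , drop = FALSE],
                             scale_rows = scale_rows)
  zc <- atanh(pmin(pmax(cc, -1 + 1e-12), 1 - 1e-12))
  structure(list(cor = cc, z = zc, hclust = hc),
            class = "psd_conn_cluster")
}
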