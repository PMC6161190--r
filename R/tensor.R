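# Abundance tensor container: positive intensities indexed by
# (protein, region, replicate) plus per-protein unique-peptide counts.

#' Construct an abundance tensor
#'
#' @param intensities 3-d numeric array `protein x region x replicate` with
#'   dimnames; all values must be finite and strictly positive.
#' @param n_unique_peptides named integer vector (>= 1) per protein.
#' @return An object of class `abundance_tensor`: a list with `intensities`,
#'   `n_unique_peptides`, `proteins`, `regions`, `replicates`.
#' @export
new_abundance_tensor <- function(intensities, n_unique_peptides) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stopf("'intensities' must be a 3-d array (protein x region x replicate)")
  dn <- dimnames(intensities)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stopf("'intensities' must carry dimnames on all three dimensions")
  bad <- which(!is.finite(intensities) | intensities <= 0)
  if (length(bad)) {
    ix <- arrayInd(bad[1], dim(intensities))
    stopf("non-positive or non-finite intensity for protein '%s', run '%s_%s'",
          dn[[1]][ix[1]], dn[[2]][ix[2]], sub("^B", "", dn[[3]][ix[3]]))
  }
  pep <- n_unique_peptides[dn[[1]]]
  if (anyNA(pep) || any(pep < 1))
    stopf("'n_unique_peptides' must cover every protein with counts >= 1")
  structure(list(intensities = intensities,
                 n_unique_peptides = setNames(as.integer(pep), dn[[1]]),
                 proteins = dn[[1]], regions = dn[[2]], replicates = dn[[3]]),
            class = "abundance_tensor")
}

#' @export
print.abundance_tensor <- function(x, ...) {
  cat(sprintf("abundance_tensor: %d proteins x %d regions x %d replicates\n",
              length(x$proteins), length(x$regions), length(x$replicates)))
  cat("  regions:", paste(x$regions, collapse = ", "), "\n")
  cat(sprintf("  intensity range: [%.3g, %.3g]; %d single-peptide proteins\n",
              min(x$intensities), max(x$intensities),
              sum(x$n_unique_peptides < 2)))
  invisible(x)
}

# Flatten to the run-column representation used on disk:
# protein_id, n_unique_peptides, then <REGION>_<k> columns.
tensor_to_frame <- function(tensor) {
  P <- length(tensor$proteins); R <- length(tensor$regions)
  K <- length(tensor$replicates)
  cols <- lapply(seq_len(R * K), function(j) {
    r <- ((j - 1) %/% K) + 1; k <- ((j - 1) %% K) + 1
    tensor$intensities[, r, k]
  })
  names(cols) <- as.vector(vapply(tensor$regions, function(r)
    paste0(r, "_", seq_len(K)), character(K)))
  cbind(data.frame(protein_id = tensor$proteins,
                   n_unique_peptides = unname(tensor$n_unique_peptides),
                   stringsAsFactors = FALSE),
        as.data.frame(cols, check.names = FALSE))
}

#' Per-region mean abundance matrix (protein x region, pooled replicates)
#'
#' @param tensor an `abundance_tensor`.
#' @param transform apply the ArcSinH transform to intensities before
#'   averaging (default FALSE: raw means, the scale used for fold changes and
#'   network edge weights).
#' @return numeric matrix `protein x region`.
#' @export
region_means <- function(tensor, transform = FALSE) {
  x <- tensor$intensities
  if (transform) x <- arcsinh_transform(x)
  apply(x, c(1, 2), mean)
}
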