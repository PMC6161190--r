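# Differential abundance: run normalization, ArcSinH transform, group
# statistics and fold changes on raw means, omnibus ANOVA and pairwise Welch
# tests on transformed values, BH adjustment, Z-score profiles, and the
# significance rules (adjusted p < alpha, >= 2 unique peptides, fold
# threshold).

#' Median-matching run normalization
#'
#' Each run (one region x replicate column of the tensor) is multiplied by a
#' single positive scalar chosen so that its median log-intensity equals that
#' of the reference run; the reference run is unchanged.
#'
#' @param tensor an `abundance_tensor`.
#' @param reference reference run id `"<REGION>_<k>"`; default the first run.
#' @return A normalized `abundance_tensor`. The applied scalars are attached
#'   as attribute `"scalars"`.
#' @export
normalize_runs <- function(tensor, reference = NULL) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  R <- length(tensor$regions); K <- length(tensor$replicates)
  run_ids <- as.vector(outer(seq_len(K), tensor$regions,
                             function(k, r) paste0(r, "_", k)))
  if (is.null(reference)) reference <- paste0(tensor$regions[1], "_1")
  if (!reference %in% run_ids)
    stopf("reference run '%s' not found (runs are e.g. '%s')", reference,
          run_ids[1])
  parse_run <- function(id) {
    m <- regmatches(id, regexec("^(.*)_([0-9]+)$", id))[[1]]
    c(region = m[2], rep = m[3])
  }
  ref <- parse_run(reference)
  x <- tensor$intensities
  med_ref <- median(log(x[, ref["region"], as.integer(ref["rep"])]))
  scalars <- matrix(NA_real_, R, K, dimnames = list(tensor$regions, NULL))
  for (r in seq_len(R)) for (k in seq_len(K)) {
    run <- x[, r, k]
    if (length(run) == 0) stopf("empty run %s_%d", tensor$regions[r], k)
    s <- exp(med_ref - median(log(run)))
    scalars[r, k] <- s
    x[, r, k] <- run * s
  }
  out <- new_abundance_tensor(x, tensor$n_unique_peptides)
  attr(out, "scalars") <- scalars
  out
}

#' ArcSinH transform
#'
#' `asinh(x) = log(x + sqrt(x^2 + 1))`: behaves like `log(2x)` for large
#' intensities but is defined and smooth at zero, the standard
#' variance-stabilizing transform for label-free intensity data.
#'
#' @param x numeric vector/array of finite values.
#' @return Transformed values, same shape.
#' @export
arcsinh_transform <- function(x) {
  if (any(!is.finite(x))) stopf("arcsinh_transform: non-finite input")
  asinh(x)
}

#' Group means and all pairwise fold changes
#'
#' Within-region means are computed on the raw (normalized, untransformed)
#' intensities and on the ArcSinH scale; fold changes are ratios of raw group
#' means, `FC(p, rA, rB) = mean_raw(p, rA) / mean_raw(p, rB)`, so that
#' `FC(rB, rA) = 1 / FC(rA, rB)` exactly.
#'
#' @param tensor an `abundance_tensor`.
#' @return A list of class `psd_group_stats`: `mean_raw` and `mean_arcsinh`
#'   (protein x region matrices) and `fold` (protein x region x region array
#'   of fold changes).
#' @export
group_stats <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  mean_raw <- region_means(tensor, transform = FALSE)
  if (any(mean_raw == 0)) stopf("zero group mean; cannot form fold-change ratio")
  mean_arcsinh <- region_means(tensor, transform = TRUE)
  R <- ncol(mean_raw)
  fold <- array(NA_real_, c(nrow(mean_raw), R, R),
                dimnames = list(rownames(mean_raw), colnames(mean_raw),
                                colnames(mean_raw)))
  for (a in seq_len(R)) for (b in seq_len(R))
    fold[, a, b] <- mean_raw[, a] / mean_raw[, b]
  structure(list(mean_raw = mean_raw, mean_arcsinh = mean_arcsinh,
                 fold = fold), class = "psd_group_stats")
}

# Row-wise one-way ANOVA F across regions on ArcSinH values. Balanced design:
# K replicates per region. Degenerate rows (zero within-group variance) get
# p = 0 when group means differ and p = 1 otherwise, with a flag.
row_anova <- function(arc) {
  P <- dim(arc)[1]; R <- dim(arc)[2]; K <- dim(arc)[3]
  if (K < 2) stopf("ANOVA needs >= 2 replicates per region")
  gm <- apply(arc, c(1, 2), mean)
  grand <- rowMeans(gm)
  ssb <- K * rowSums((gm - grand)^2)
  ssw <- numeric(P)
  for (r in seq_len(R)) {
    slice <- arc[, r, , drop = FALSE]
    dim(slice) <- c(P, K)
    ssw <- ssw + rowSums((slice - gm[, r])^2)
  }
  df1 <- R - 1; df2 <- R * (K - 1)
  Fv <- (ssb / df1) / (ssw / df2)
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  degen <- ssw == 0
  p[degen] <- ifelse(ssb[degen] > 0, 0, 1)
  data.frame(protein_id = rownames(gm), F = Fv, df1 = df1, df2 = df2,
             p = p, degenerate = degen, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Row-wise Welch two-sample t between two region slices (P x K matrices).
row_welch <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(mx[degen] != my[degen], 0, 1)
  t[degen] <- ifelse(mx[degen] != my[degen], Inf * sign(mx - my)[degen], 0)
  list(t = t, df = df, p = p, degenerate = degen)
}

#' Omnibus ANOVA and pairwise Welch tests on ArcSinH abundances
#'
#' Per protein: a one-way ANOVA F across regions on the transformed values,
#' and a Welch two-sample t for every unordered region pair. p-values are
#' BH-adjusted across proteins (within the omnibus family and within each
#' pairwise contrast, respectively). Rows with zero within-group variance are
#' flagged `degenerate` and get p = 0 (means differ) or p = 1 (all equal).
#'
#' @param tensor an `abundance_tensor` (>= 2 replicates per region).
#' @return A list of class `psd_tests`: `anova` (per-protein data.frame with
#'   `F`, `p`, `p_adj`, `degenerate`) and `pairwise` (long data.frame with
#'   `protein_id`, `region_a`, `region_b`, `t`, `p`, `p_adj`, `degenerate`).
#' @export
anova_and_pairwise <- function(tensor) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  arc <- arcsinh_transform(tensor$intensities)
  anova <- row_anova(arc)
  anova$p_adj <- bh_adjust(anova$p)
  R <- length(tensor$regions)
  P <- length(tensor$proteins); K <- length(tensor$replicates)
  region_slice <- function(r) {
    m <- arc[, r, , drop = FALSE]
    dim(m) <- c(P, K)
    m
  }
  pairs <- utils::combn(R, 2)
  pw <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- row_welch(region_slice(a), region_slice(b))
    pw[[j]] <- data.frame(protein_id = tensor$proteins,
                          region_a = tensor$regions[a],
                          region_b = tensor$regions[b],
                          t = res$t, df = res$df, p = res$p,
                          p_adj = bh_adjust(res$p),
                          degenerate = res$degenerate,
                          stringsAsFactors = FALSE)
  }
  structure(list(anova = anova, pairwise = do.call(rbind, pw)),
            class = "psd_tests")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`; kept as a named
#' operation so the adjustment used throughout the pipeline is a single
#' swappable point.
#'
#' @param pvals numeric vector of p-values in [0, 1] (may be empty).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Z-score a per-region profile
#'
#' Centers and scales (sample sd, n - 1) a vector of per-region ArcSinH mean
#' abundances. A constant profile cannot be scaled: it returns all zeros with
#' attribute `flagged = TRUE`.
#'
#' @param x numeric vector (>= 2 regions) or a protein x region matrix (rows
#'   are scored independently; flags returned as an attribute vector).
#' @return z-scores, same shape as `x`.
#' @export
zscore_profile <- function(x) {
  if (is.matrix(x)) {
    z <- t(apply(x, 1, zscore_profile))
    dimnames(z) <- dimnames(x)
    attr(z, "flagged") <- apply(x, 1, function(r) sd(r) == 0)
    return(z)
  }
  if (length(x) < 2) stopf("zscore_profile needs >= 2 regions")
  s <- sd(x)
  if (s == 0) return(structure(rep(0, length(x)), flagged = TRUE,
                               names = names(x)))
  structure((x - mean(x)) / s, flagged = FALSE, names = names(x))
}

#' Apply the differential-expression significance rules
#'
#' A protein is differentially expressed (DE) for region `r` when some
#' contrast against another region satisfies all three rules: BH-adjusted
#' pairwise p below `alpha`, at least `min_peptides` unique peptides, and a
#' fold change of at least `fold_threshold` (up) or at most
#' `1/fold_threshold` (down).
#'
#' @param stats a `psd_group_stats` from [group_stats()].
#' @param tests a `psd_tests` from [anova_and_pairwise()].
#' @param peptides named integer vector of unique-peptide counts.
#' @param fold_threshold fold-change threshold (> 1), default 1.5; 1.3 is the
#'   documented alternative.
#' @param alpha significance level on adjusted pairwise p-values.
#' @param min_peptides minimum unique peptides (default 2).
#' @param compare `"all"` (default): a protein is a region's DE marker only
#'   when it passes against every other region (regional signature sets,
#'   whose union is the headline DE count); `"any"`: one qualifying contrast
#'   suffices.
#' @return A list of class `psd_de`: `table` (per protein x contrast with
#'   `fold_change`, `p`, `p_adj`, `z_a`, `passes`), `regions` (list of
#'   per-region DE protein sets), `up`/`down` per-region sets, `counts`
#'   per-region counts, `de_proteins` (union), `n_de`, `frac_de`.
#' @export
de_filter <- function(stats, tests, peptides, fold_threshold = 1.5,
                      alpha = 0.05, min_peptides = 2,
                      compare = c("all", "any")) {
  compare <- match.arg(compare)
  stopifnot(inherits(stats, "psd_group_stats"), inherits(tests, "psd_tests"))
  if (fold_threshold <= 1) stopf("'fold_threshold' must be > 1")
  pw <- tests$pairwise
  z <- zscore_profile(stats$mean_arcsinh)
  fc <- stats$fold[cbind(match(pw$protein_id, rownames(stats$mean_raw)),
                         match(pw$region_a, colnames(stats$mean_raw)),
                         match(pw$region_b, colnames(stats$mean_raw)))]
  pep_ok <- peptides[pw$protein_id] >= min_peptides
  sig <- pw$p_adj < alpha
  up <- fc >= fold_threshold
  down <- fc <= 1 / fold_threshold
  tab <- data.frame(pw[c("protein_id", "region_a", "region_b")],
                    fold_change = fc, p = pw$p, p_adj = pw$p_adj,
                    z_a = z[cbind(match(pw$protein_id, rownames(z)),
                                  match(pw$region_a, colnames(z)))],
                    passes = sig & pep_ok & (up | down),
                    direction = ifelse(up, "up", ifelse(down, "down", "none")),
                    stringsAsFactors = FALSE)
  regions <- colnames(stats$mean_raw)
  proteins <- rownames(stats$mean_raw)
  per_region <- up_sets <- down_sets <- setNames(vector("list",
                                                        length(regions)),
                                                 regions)
  # per-protein pass/direction matrices oriented as (protein, r, r')
  R <- length(regions)
  pass_up <- pass_down <- array(FALSE, c(length(proteins), R, R),
                                dimnames = list(proteins, regions, regions))
  ok <- tab$passes
  ia <- match(tab$protein_id, proteins)
  ra <- match(tab$region_a, regions)
  rb <- match(tab$region_b, regions)
  up_ok <- ok & tab$direction == "up"
  down_ok <- ok & tab$direction == "down"
  pass_up[cbind(ia[up_ok], ra[up_ok], rb[up_ok])] <- TRUE
  pass_up[cbind(ia[down_ok], rb[down_ok], ra[down_ok])] <- TRUE
  pass_down[cbind(ia[down_ok], ra[down_ok], rb[down_ok])] <- TRUE
  pass_down[cbind(ia[up_ok], rb[up_ok], ra[up_ok])] <- TRUE
  slice <- function(arr, r, others) {
    m <- arr[, r, others, drop = FALSE]
    dim(m) <- c(length(proteins), length(others))
    m
  }
  for (r in seq_along(regions)) {
    others <- setdiff(seq_len(R), r)
    agg <- if (compare == "all") function(m) rowSums(m) == length(others)
           else function(m) rowSums(m) > 0
    up_sets[[regions[r]]] <- proteins[agg(slice(pass_up, r, others))]
    down_sets[[regions[r]]] <- proteins[agg(slice(pass_down, r, others))]
    per_region[[regions[r]]] <- sort(unique(c(up_sets[[regions[r]]],
                                              down_sets[[regions[r]]])))
  }
  de_proteins <- sort(unique(unlist(per_region)))
  structure(list(table = tab, regions = per_region, up = up_sets,
                 down = down_sets,
                 counts = vapply(per_region, length, integer(1)),
                 de_proteins = de_proteins, n_de = length(de_proteins),
                 frac_de = length(de_proteins) /
                   nrow(stats$mean_raw),
                 fold_threshold = fold_threshold, alpha = alpha,
                 min_peptides = min_peptides, compare = compare),
            class = "psd_de")
}

#' @export
print.psd_de <- function(x, ...) {
  cat(sprintf(
    "psd_de: %d DE proteins (%.1f%%) at fold >= %g (or <= %.3g), p_adj < %g, peptides >= %d\n",
    x$n_de, 100 * x$frac_de, x$fold_threshold, 1 / x$fold_threshold,
    x$alpha, x$min_peptides))
  print(x$counts)
  invisible(x)
}

#' One-shot differential-abundance analysis of a tensor
#'
#' Normalizes runs, computes group statistics, omnibus and pairwise tests,
#' and applies the DE rules.
#'
#' @param tensor an `abundance_tensor`.
#' @param reference reference run for normalization (default first run).
#' @inheritParams de_filter
#' @param normalize logical; set FALSE if the tensor is already normalized.
#' @return A list of class `psd_quantify` with elements `tensor` (normalized),
#'   `stats`, `tests`, `de`, `z` (protein x region Z-score matrix).
#' @export
quantify_regions <- function(tensor, reference = NULL, fold_threshold = 1.5,
                             alpha = 0.05, min_peptides = 2,
                             normalize = TRUE, compare = c("all", "any")) {
  if (normalize) tensor <- normalize_runs(tensor, reference)
  stats <- group_stats(tensor)
  tests <- anova_and_pairwise(tensor)
  de <- de_filter(stats, tests, tensor$n_unique_peptides,
                  fold_threshold = fold_threshold, alpha = alpha,
                  min_peptides = min_peptides, compare = compare)
  structure(list(tensor = tensor, stats = stats, tests = tests, de = de,
                 z = zscore_profile(stats$mean_arcsinh)),
            class = "psd_quantify")
}

#' @export
print.psd_quantify <- function(x, ...) {
  cat(sprintf("psd_quantify: %d proteins, %d regions\n",
              nrow(x$stats$mean_raw), ncol(x$stats$mean_raw)))
  print(x$de)
  invisible(x)
}
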