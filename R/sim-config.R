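#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [simulate_all()]: a positive
#' abundance tensor of `n_proteins` proteins measured in `n_regions` brain
#' regions for `n_replicates` individual brains, with planted region-specific
#' differential-expression effects, planted co-abundance modules, an
#' SBM-like PPI graph aligned to the modules, a connectome projection-volume
#' matrix linearly coupled to a subset of proteins, and a small ontology DAG
#' annotated to the planted modules.
#'
#' Defaults mirror the scale of a seven-region, six-brain postsynaptic
#' proteome study quantified to 1173 proteins with a PPI network of roughly
#' a thousand nodes and eight thousand interactions.
#'
#' @param n_proteins,n_regions,n_replicates,n_modules tensor dimensions and
#'   number of planted co-abundance modules.
#' @param frac_de fraction of proteins carrying a planted differential effect
#'   in exactly one region.
#' @param effect_fold multiplicative fold (> 1) of the planted effect; planted
#'   directions are up (`effect_fold`) or down (`1/effect_fold`) with equal
#'   probability.
#' @param noise_cv multiplicative measurement noise, expressed as a
#'   coefficient of variation; log-scale sd is `log(1 + noise_cv)`.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-protein baseline intensity.
#' @param module_fold scale of the per-(module, region) co-abundance effects;
#'   1 disables them. Kept below the differential-expression fold threshold by
#'   default so module structure does not masquerade as planted DE.
#' @param ppi_p_in,ppi_p_out within/between-community edge probabilities of
#'   the planted-partition PPI graph (communities = modules).
#' @param frac_coupled fraction of proteins whose regional profile follows the
#'   latent connectivity profile (connectome coupling).
#' @param couple_fold spread of the latent connectivity profile across regions.
#' @param couple_noise coefficient of variation of the noise on connectome
#'   matrix entries.
#' @param frac_unstable fraction of proteins whose regional profile is
#'   independently permuted in every brain (low differential stability).
#' @param frac_single_peptide fraction of proteins reported with a single
#'   unique peptide (to exercise the peptide filter). Default 0: the emulated
#'   dataset is pre-filtered to proteins with at least two unique peptides.
#' @param n_terms number of ontology terms (>= 3).
#' @param n_shared_regions the first `n_shared_regions` regions share a
#'   correlated component of their module effects (a planted "cortex-like"
#'   clade); 0 disables.
#' @param region_names character vector of region labels, or NULL for the
#'   seven default labels (CxF, CxM, CxCA, Hip, ST, Hyp, CB) truncated or
#'   extended to `n_regions`.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_all()], [simulate_abundance()]
#' @export
sim_config <- function(n_proteins = 1173, n_regions = 7, n_replicates = 6,
                       n_modules = 6, frac_de = 0.3, effect_fold = 2,
                       noise_cv = 0.1,
                       baseline_log_mean = 13.8, baseline_log_sd = 1.5,
                       module_fold = 1.15,
                       ppi_p_in = 0.05, ppi_p_out = 0.004,
                       frac_coupled = 0.1, couple_fold = 1.5,
                       couple_noise = 0.1,
                       frac_unstable = 0, frac_single_peptide = 0,
                       n_terms = 60, n_shared_regions = 3,
                       region_names = NULL, seed = 1L) {
  cfg <- list(
    n_proteins = assert_count(n_proteins, "n_proteins"),
    n_regions = assert_count(n_regions, "n_regions"),
    n_replicates = assert_count(n_replicates, "n_replicates"),
    n_modules = assert_count(n_modules, "n_modules"),
    frac_de = assert_fraction(frac_de, "frac_de"),
    effect_fold = assert_nonneg(effect_fold, "effect_fold"),
    noise_cv = assert_nonneg(noise_cv, "noise_cv"),
    baseline_log_mean = as.numeric(baseline_log_mean),
    baseline_log_sd = assert_nonneg(baseline_log_sd, "baseline_log_sd"),
    module_fold = assert_nonneg(module_fold, "module_fold"),
    ppi_p_in = assert_fraction(ppi_p_in, "ppi_p_in"),
    ppi_p_out = assert_fraction(ppi_p_out, "ppi_p_out"),
    frac_coupled = assert_fraction(frac_coupled, "frac_coupled"),
    couple_fold = assert_nonneg(couple_fold, "couple_fold"),
    couple_noise = assert_nonneg(couple_noise, "couple_noise"),
    frac_unstable = assert_fraction(frac_unstable, "frac_unstable"),
    frac_single_peptide = assert_fraction(frac_single_peptide,
                                          "frac_single_peptide"),
    n_terms = assert_count(n_terms, "n_terms"),
    n_shared_regions = as.integer(assert_nonneg(n_shared_regions,
                                                "n_shared_regions")),
    seed = as.integer(seed)
  )
  if (cfg$effect_fold < 1)
    stopf("'effect_fold' must be >= 1 (got %g)", cfg$effect_fold)
  if (cfg$module_fold < 1)
    stopf("'module_fold' must be >= 1 (got %g)", cfg$module_fold)
  if (cfg$n_modules > cfg$n_proteins)
    stopf("'n_modules' cannot exceed 'n_proteins'")
  if (cfg$n_terms < 3) stopf("'n_terms' must be >= 3")
  if (is.null(region_names)) {
    base <- c("CxF", "CxM", "CxCA", "Hip", "ST", "Hyp", "CB")
    region_names <- if (cfg$n_regions <= length(base)) base[seq_len(cfg$n_regions)]
      else c(base, paste0("R", seq_len(cfg$n_regions - length(base)) + length(base)))
  }
  if (length(region_names) != cfg$n_regions || anyDuplicated(region_names))
    stopf("'region_names' must be %d unique labels", cfg$n_regions)
  cfg$region_names <- as.character(region_names)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d proteins x %d regions x %d replicates, %d modules\n",
    x$n_proteins, x$n_regions, x$n_replicates, x$n_modules))
  cat(sprintf("  DE: %.0f%% of proteins at fold %g; noise cv %g; seed %d\n",
              100 * x$frac_de, x$effect_fold, x$noise_cv, x$seed))
  cat(sprintf("  PPI: p_in %g / p_out %g; coupled %.0f%%; terms %d\n",
              x$ppi_p_in, x$ppi_p_out, 100 * x$frac_coupled, x$n_terms))
  invisible(x)
}
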