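# Synthetic-data generator: every pipeline input with planted ground truth.
# One global seed is split into per-component substreams (abundance / PPI /
# connectome / ontology) so regenerating one component leaves the others
# untouched.

#' Simulate a regional protein abundance tensor with planted ground truth
#'
#' Generates positive intensities
#' `intensity(p, r, k) = baseline(p) * moduleEffect(module(p), r) *
#' deEffect(p, r) * exp(eps)` with `eps ~ N(0, log(1 + noise_cv))`,
#' log-normal baselines, per-(module, region) co-abundance effects, planted
#' differential effects of fold `effect_fold` (or its reciprocal) in one
#' region for a `frac_de` fraction of proteins, a `frac_coupled` fraction of
#' proteins following the latent connectivity profile, and a `frac_unstable`
#' fraction whose regional profile is re-permuted in every brain.
#'
#' @param config a [sim_config()] object.
#' @return A list with `tensor` (an `abundance_tensor`) and `truth`
#'   (a `sim_truth` with `de`, `module_labels`, `community_labels`,
#'   `coupled`, `unstable`, `couple_profile`, `module_effects`).
#' @export
simulate_abundance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$n_proteins; R <- config$n_regions; K <- config$n_replicates
  with_seed(derive_seed(config$seed, 1), {
    proteins <- sprintf("P%05d", seq_len(P))
    regions <- config$region_names
    replicates <- paste0("B", seq_len(K))

    module_labels <- setNames(sample(rep_len(seq_len(config$n_modules), P)),
                              proteins)

    n_coupled <- round(config$frac_coupled * P)
    coupled <- sort(sample(P, n_coupled))
    pool <- setdiff(seq_len(P), coupled)
    n_unstable <- min(round(config$frac_unstable * P), length(pool))
    unstable <- sort(sample(pool, n_unstable))
    pool <- setdiff(pool, unstable)
    n_de <- min(round(config$frac_de * P), length(pool))
    de_idx <- sort(sample(pool, n_de))
    de_region <- sample(regions, n_de, replace = TRUE)
    de_dir <- sample(c(1, -1), n_de, replace = TRUE)
    de_fold <- config$effect_fold ^ de_dir

    # Module effects: regions in the leading "shared" block draw a common
    # component, emulating anatomically related regions with similar module
    # abundance; independent component on top.
    lm_mod <- log(config$module_fold)
    nsr <- config$n_shared_regions
    group <- if (nsr >= 2 && R > nsr) c(rep(1L, nsr), seq_len(R - nsr) + 1L)
             else seq_len(R)
    shared <- matrix(rnorm(config$n_modules * max(group), 0, lm_mod),
                     config$n_modules)
    indiv <- matrix(rnorm(config$n_modules * R, 0, 0.4 * lm_mod),
                    config$n_modules)
    log_me <- shared[, group, drop = FALSE] + indiv
    dimnames(log_me) <- list(seq_len(config$n_modules), regions)

    couple_profile <- setNames(exp(rnorm(R, 0, log(config$couple_fold))),
                               regions)

    # Per-protein log regional effect.
    E <- log_me[module_labels, , drop = FALSE]
    if (n_coupled > 0)
      E[coupled, ] <- matrix(log(couple_profile), n_coupled, R, byrow = TRUE)
    if (n_de > 0)
      E[cbind(de_idx, match(de_region, regions))] <-
        E[cbind(de_idx, match(de_region, regions))] + log(de_fold)

    baseline <- rnorm(P, config$baseline_log_mean, config$baseline_log_sd)

    eff <- array(E, dim = c(P, R, K))
    if (n_unstable > 0) {
      for (p in unstable) for (k in seq_len(K))
        eff[p, , k] <- E[p, sample(R)]
    }
    sd_log <- log1p(config$noise_cv)
    noise <- array(rnorm(P * R * K, 0, sd_log), dim = c(P, R, K))
    intens <- exp(array(baseline, dim = c(P, R, K)) + eff + noise)
    dimnames(intens) <- list(proteins, regions, replicates)

    peptides <- setNames(2L + rpois(P, 6), proteins)
    n_single <- round(config$frac_single_peptide * P)
    if (n_single > 0) peptides[sample(P, n_single)] <- 1L

    tensor <- new_abundance_tensor(intens, peptides)
    truth <- structure(list(
      de = data.frame(protein_id = proteins[de_idx], region = de_region,
                      fold = de_fold, stringsAsFactors = FALSE),
      module_labels = module_labels,
      community_labels = module_labels,
      coupled = proteins[coupled],
      unstable = proteins[unstable],
      couple_profile = couple_profile,
      module_effects = exp(log_me)
    ), class = "sim_truth")
    list(tensor = tensor, truth = truth)
  })
}

#' Simulate a planted-partition (SBM-like) PPI edge list
#'
#' Undirected simple graph over the proteins: a pair inside one planted
#' community is an edge with probability `ppi_p_in`, a pair spanning two
#' communities with probability `ppi_p_out`. No self-loops or duplicates.
#'
#' @param config a [sim_config()] object.
#' @param truth ground truth from [simulate_abundance()] (supplies the
#'   community labels).
#' @return A data.frame with columns `protein_a`, `protein_b`.
#' @export
simulate_ppi <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  comm <- truth$community_labels
  proteins <- names(comm)
  P <- length(comm)
  if (P < 2)
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  with_seed(derive_seed(config$seed, 2), {
    idx <- which(upper.tri(matrix(FALSE, P, P)), arr.ind = TRUE)
    same <- comm[idx[, 1]] == comm[idx[, 2]]
    p <- ifelse(same, config$ppi_p_in, config$ppi_p_out)
    keep <- runif(nrow(idx)) < p
    data.frame(protein_a = proteins[idx[keep, 1]],
               protein_b = proteins[idx[keep, 2]],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a region-by-region connectome projection-volume matrix
#'
#' Builds a non-negative matrix whose row means (the connectivity vector,
#' diagonal included) follow the latent connectivity profile that the
#' coupled proteins' regional abundances were drawn from, so that with zero
#' coupling noise every coupled protein is perfectly correlated with the
#' connectivity vector.
#'
#' @param config a [sim_config()] object.
#' @param truth ground truth from [simulate_abundance()].
#' @param tensor the abundance tensor (dimension check only).
#' @return A named `n_regions x n_regions` non-negative matrix.
#' @export
simulate_connectome <- function(config, truth, tensor) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  regions <- config$region_names
  R <- length(regions)
  with_seed(derive_seed(config$seed, 3), {
    v <- 100 * truth$couple_profile / mean(truth$couple_profile)
    w <- exp(rnorm(R, 0, 0.25))
    w <- w / mean(w)
    M <- outer(unname(v), w)
    if (config$couple_noise > 0)
      M <- M * exp(matrix(rnorm(R * R, 0, log1p(config$couple_noise)), R))
    dimnames(M) <- list(regions, regions)
    M
  })
}

#' Simulate an ontology DAG and protein annotations aligned to modules
#'
#' Builds a rooted is-a DAG (root, a mid layer, leaves; some leaves have two
#' parents) and annotates one leaf per planted module with most of that
#' module's proteins, so enrichment of a module against its planted term is
#' recoverable. Remaining leaves get random background annotations.
#'
#' @param config a [sim_config()] object.
#' @param truth ground truth from [simulate_abundance()].
#' @return A list with `ontology` (a `psd_ontology`), `annotations`
#'   (data.frame `protein_id`, `term_id`; direct annotations only) and
#'   `planted_terms` (term id per module).
#' @export
simulate_ontology <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  nt <- config$n_terms
  proteins <- names(truth$module_labels)
  with_seed(derive_seed(config$seed, 4), {
    ids <- sprintf("T%04d", seq_len(nt))
    n_mid <- max(1L, min(round((nt - 1) / 4), nt - 2L))
    mid <- ids[1L + seq_len(n_mid)]
    leaves <- ids[-seq_len(1L + n_mid)]
    parents <- c(list(character()),
                 rep(list(ids[1]), n_mid),
                 lapply(leaves, function(l) {
                   p <- sample(mid, 1)
                   if (length(mid) > 1 && runif(1) < 0.3)
                     p <- c(p, sample(setdiff(mid, p), 1))
                   p
                 }))
    names(parents) <- ids
    onto <- new_ontology(
      terms = data.frame(id = ids,
                         name = c("root process",
                                  paste("branch", seq_len(n_mid)),
                                  paste("leaf process", seq_along(leaves))),
                         stringsAsFactors = FALSE),
      parents = parents)

    n_planted <- min(config$n_modules, length(leaves))
    planted_terms <- setNames(leaves[seq_len(n_planted)],
                              seq_len(n_planted))
    ann <- list()
    for (m in seq_len(n_planted)) {
      members <- proteins[truth$module_labels == m]
      take <- sample(members, max(1, round(0.8 * length(members))))
      ann[[length(ann) + 1L]] <- data.frame(protein_id = take,
                                            term_id = planted_terms[[m]],
                                            stringsAsFactors = FALSE)
    }
    for (l in setdiff(leaves, planted_terms)) {
      size <- min(length(proteins), max(3, rpois(1, 15)))
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = sample(proteins, size), term_id = l,
        stringsAsFactors = FALSE)
    }
    annotations <- unique(do.call(rbind, ann))
    annotations <- annotations[order(annotations$term_id,
                                     annotations$protein_id), ]
    rownames(annotations) <- NULL
    list(ontology = onto, annotations = annotations,
         planted_terms = planted_terms)
  })
}

#' Generate all pipeline inputs from one configuration
#'
#' @param config a [sim_config()] object.
#' @return A list with `config`, `tensor`, `truth`, `edges`, `connectome`,
#'   `ontology`, `annotations`, `planted_terms`.
#' @examples
#' sim <- simulate_all(sim_config(n_proteins = 60, n_terms = 12, seed = 7))
#' dim(sim$tensor$intensities)
#' @export
simulate_all <- function(config = sim_config()) {
  ab <- simulate_abundance(config)
  edges <- simulate_ppi(config, ab$truth)
  connectome <- simulate_connectome(config, ab$truth, ab$tensor)
  onto <- simulate_ontology(config, ab$truth)
  list(config = config, tensor = ab$tensor, truth = ab$truth, edges = edges,
       connectome = connectome, ontology = onto$ontology,
       annotations = onto$annotations, planted_terms = onto$planted_terms)
}

#' Write all simulated inputs (and the ground-truth sidecar) to a directory
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(sim$config)
  write_abundance(sim$tensor, file.path(dir, "abundance.tsv"), config = cfg)
  write_tsv(sim$edges, file.path(dir, "ppi_edges.tsv"), config = cfg)
  write_connectome(sim$connectome, file.path(dir, "connectome.csv"))
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  write_tsv(sim$annotations, file.path(dir, "annotations.tsv"), config = cfg)
  tr <- sim$truth
  gt <- data.frame(protein_id = names(tr$module_labels),
                   module = unname(tr$module_labels),
                   community = unname(tr$community_labels),
                   de_region = NA_character_, de_fold = 1,
                   coupled = names(tr$module_labels) %in% tr$coupled,
                   unstable = names(tr$module_labels) %in% tr$unstable,
                   stringsAsFactors = FALSE)
  i <- match(tr$de$protein_id, gt$protein_id)
  gt$de_region[i] <- tr$de$region
  gt$de_fold[i] <- tr$de$fold
  write_tsv(gt, file.path(dir, "ground_truth.tsv"), config = cfg)
  invisible(dir)
}
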