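# Pipeline orchestration: simulate (or ingest) -> quantify -> signatures ->
# network -> core -> connectome -> enrichment, writing each stage's outputs
# before the next starts and a machine-readable JSON run report at the end.

#' Full pipeline configuration
#'
#' Bundles the synthetic-data configuration with every analysis threshold.
#' All thresholds sit at their conventional defaults: pairwise adjusted
#' p < 0.05, fold change 1.5 (1.3 is the documented alternative), >= 2 unique
#' peptides, stability score <= 2, r-squared >= 0.6, elimination alpha 0.01.
#'
#' @param sim a [sim_config()]; ignored when `inputs` point at files.
#' @param alpha significance level for adjusted pairwise p-values.
#' @param fold_threshold differential-expression fold threshold (> 1).
#' @param min_peptides minimum unique peptides for DE calls.
#' @param ds_cutoff differential-stability cutoff (NULL = median).
#' @param r2_threshold connectome-correlation selection threshold.
#' @param max_score maximum stability score for the stable core network.
#' @param alpha_elim elimination threshold for elim-Fisher enrichment.
#' @param ppm_k fixed module count (NULL = select via `k_range`).
#' @param k_range candidate module counts for [choose_k()].
#' @param reference reference run for normalization (NULL = first run).
#' @param inputs optional named list of file paths (`abundance`, `edges`,
#'   `connectome`, `obo`, `annotations`) to ingest instead of simulating.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), alpha = 0.05, fold_threshold = 1.5,
                       min_peptides = 2, ds_cutoff = NULL, r2_threshold = 0.6,
                       max_score = 2, alpha_elim = 0.01, ppm_k = NULL,
                       k_range = 2:8, reference = NULL, inputs = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (alpha <= 0 || alpha > 1) stopf("'alpha' must be in (0, 1]")
  if (fold_threshold <= 1) stopf("'fold_threshold' must be > 1")
  if (r2_threshold < 0 || r2_threshold > 1)
    stopf("'r2_threshold' must be in [0, 1]")
  if (max_score < 0) stopf("'max_score' must be >= 0")
  if (!is.null(inputs)) {
    missing <- !vapply(unlist(inputs), file.exists, logical(1))
    if (any(missing))
      stopf("input file not found: %s", unlist(inputs)[missing][1])
  }
  structure(list(sim = sim, alpha = alpha, fold_threshold = fold_threshold,
                 min_peptides = min_peptides, ds_cutoff = ds_cutoff,
                 r2_threshold = r2_threshold, max_score = max_score,
                 alpha_elim = alpha_elim, ppm_k = ppm_k, k_range = k_range,
                 reference = reference, inputs = inputs),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `sim` section
#' mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  y$sim <- NULL
  do.call(run_config, c(list(sim = sim), y))
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[psdregions] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> quantify -> signatures -> network ->
#' core -> connectome -> enrichment. Every stage's files are written to
#' `outdir` before the next stage starts; a failure aborts with the stage
#' name, preserving completed outputs. The JSON run report
#' (`run_report.json`) carries counts per stage, modularity per region, the
#' stable fraction, the module count, versions, seed and a config echo - and
#' no timestamps, so identical configurations yield byte-identical reports.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param seed optional integer overriding the simulation seed.
#' @param verbose log per-stage progress to stderr.
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(config = run_config(), outdir, seed = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  cfg_plain$sim <- unclass(cfg_plain$sim)
  report <- list(tool = "psdregions",
                 version = as.character(utils::packageVersion("psdregions")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = config$sim$seed,
                 config_md5 = config_hash(cfg_plain),
                 config = cfg_plain,
                 stages = list())
  stage <- function(name, code) {
    log_msg(verbose, "stage %s ...", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log_msg(verbose, "stage %s done (%.1f s)", name,
            proc.time()[["elapsed"]] - t0)
    res
  }

  # -- simulate / ingest ----------------------------------------------------
  sim <- stage("simulate", {
    if (is.null(config$inputs)) {
      s <- simulate_all(config$sim)
      write_simulation(s, file.path(outdir, "input"))
      s
    } else {
      inp <- config$inputs
      ann <- if (!is.null(inp$annotations)) read_annotations(inp$annotations)
      list(tensor = read_abundance(inp$abundance),
           edges = read_edges(inp$edges),
           connectome = if (!is.null(inp$connectome))
             read_connectome(inp$connectome),
           ontology = if (!is.null(inp$obo)) read_obo(inp$obo),
           annotations = ann, truth = NULL)
    }
  })
  report$stages$simulate <- list(
    n_proteins = length(sim$tensor$proteins),
    n_regions = length(sim$tensor$regions),
    n_replicates = length(sim$tensor$replicates),
    n_ppi_edges = nrow(sim$edges))

  # -- quantify -------------------------------------------------------------
  q <- stage("quantify", {
    qq <- quantify_regions(sim$tensor, reference = config$reference,
                           fold_threshold = config$fold_threshold,
                           alpha = config$alpha,
                           min_peptides = config$min_peptides)
    write_tsv(qq$de$table, file.path(outdir, "de_table.tsv"),
              config = cfg_plain)
    jsonlite::write_json(list(counts = as.list(qq$de$counts),
                              n_de = qq$de$n_de, frac_de = qq$de$frac_de),
                         file.path(outdir, "de_summary.json"),
                         auto_unbox = TRUE, digits = 10)
    qq
  })
  report$stages$quantify <- list(n_de = q$de$n_de,
                                 frac_de = q$de$frac_de,
                                 counts = as.list(q$de$counts))

  # -- signatures -----------------------------------------------------------
  sig <- stage("signatures", {
    ds <- differential_stability(q$tensor)
    high <- select_high_ds(ds, config$ds_cutoff)
    ppm <- detect_ppms(q$stats$mean_raw, k = config$ppm_k,
                       k_range = config$k_range)
    presence <- region_presence(q$stats$mean_raw)
    links <- circos_links(ppm$labels, presence)
    write_tsv(ds, file.path(outdir, "ds_table.tsv"), config = cfg_plain)
    write_tsv(data.frame(protein_id = names(ppm$labels),
                         module = unname(ppm$labels)),
              file.path(outdir, "ppm_assignment.tsv"), config = cfg_plain)
    write_newick(ppm$hclust$row_hclust,
                 file.path(outdir, "protein_dendrogram.nwk"))
    if (!is.null(ppm$hclust$col_hclust))
      write_newick(ppm$hclust$col_hclust,
                   file.path(outdir, "region_dendrogram.nwk"))
    write_circos(links, q$tensor$regions, file.path(outdir, "circos"))
    # module-ranked abundance per region
    rank_tab <- do.call(rbind, lapply(q$tensor$regions, function(r) {
      ord <- order(-q$stats$mean_raw[, r])
      data.frame(region = r, protein_id = rownames(q$stats$mean_raw)[ord],
                 module = unname(ppm$labels[ord]), rank = seq_along(ord),
                 abundance = q$stats$mean_raw[ord, r],
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rank_tab, file.path(outdir, "module_ranked_abundance.tsv"),
              config = cfg_plain)
    list(ds = ds, high = high, ppm = ppm, links = links)
  })
  report$stages$signatures <- list(
    ppm_k = sig$ppm$K,
    n_high_ds = length(sig$high),
    ds_range = range(sig$ds$avg_cor, na.rm = TRUE),
    n_links = nrow(sig$links))

  # -- network --------------------------------------------------------------
  net <- stage("network", {
    nw <- build_network(sim$edges, q$tensor$proteins)
    rg <- weight_edges(nw, q$stats$mean_raw)
    parts <- cluster_all_regions(rg)
    for (r in names(parts$partitions))
      write_tsv(data.frame(protein_id = nw$nodes,
                           community = unname(parts$partitions[[r]]$membership)),
                file.path(outdir, sprintf("partition_%s.tsv", r)),
                config = cfg_plain)
    write_tsv(parts$summary, file.path(outdir, "network_summary.tsv"),
              config = cfg_plain)
    write_gexf(nw$nodes, nw$edges, file.path(outdir, "network.gexf"),
               membership = parts$partitions[[1]]$membership,
               weights = rg$weights)
    list(network = nw, rg = rg, parts = parts)
  })
  report$stages$network <- list(
    n_nodes = length(net$network$nodes),
    n_edges = nrow(net$network$edges),
    dropped = as.list(net$network$dropped),
    n_communities = as.list(setNames(net$parts$summary$n_communities,
                                     net$parts$summary$region)),
    Q = as.list(setNames(net$parts$summary$Q, net$parts$summary$region)))

  # -- core (stable network) ------------------------------------------------
  core <- stage("core", {
    scores <- stability_scores(net$parts, net$network$edges)
    overall <- rowMeans(q$stats$mean_raw)
    w_overall <- (overall[net$network$edges$protein_a] +
                    overall[net$network$edges$protein_b]) / 2
    stable <- select_stable(scores, max_score = config$max_score,
                            weights = unname(w_overall))
    write_tsv(scores, file.path(outdir, "stability_scores.tsv"),
              config = cfg_plain)
    write_tsv(stable$edges, file.path(outdir, "stable_edges.tsv"),
              config = cfg_plain)
    overlap <- NULL
    if (!is.null(stable$partition)) {
      write_gexf(names(stable$partition$membership),
                 stable$edges[c("protein_a", "protein_b")],
                 file.path(outdir, "stable_network.gexf"),
                 membership = stable$partition$membership)
      overlap <- module_overlap(stable$partition$membership, sig$ppm$labels,
                                universe = q$tensor$proteins)
      write_tsv(overlap, file.path(outdir, "stable_ppm_overlap.tsv"),
                config = cfg_plain)
    }
    list(scores = scores, stable = stable, overlap = overlap)
  })
  report$stages$core <- list(
    n_stable = core$stable$n_stable,
    stable_fraction = core$stable$fraction,
    n_stable_clusters = if (!is.null(core$stable$partition))
      core$stable$partition$n_communities else 0L,
    stable_Q = if (!is.null(core$stable$partition))
      core$stable$partition$Q else NA)

  # -- connectome -----------------------------------------------------------
  conn <- stage("connectome", {
    if (is.null(sim$connectome)) return(NULL)
    v <- connectivity_vector(sim$connectome)
    cors <- correlate_proteins(q$stats$mean_raw, v,
                               r2_threshold = config$r2_threshold)
    cc <- correlation_cluster(q$stats$mean_raw, sim$connectome)
    write_tsv(cors, file.path(outdir, "connectome_correlation.tsv"),
              config = cfg_plain)
    write_tsv(cbind(data.frame(protein_id = rownames(cc$z)),
                    as.data.frame(cc$z)),
              file.path(outdir, "connectome_z_matrix.tsv"),
              config = cfg_plain)
    list(vector = v, cors = cors, cc = cc)
  })
  report$stages$connectome <- if (is.null(conn)) list(skipped = TRUE) else
    list(n_selected = sum(conn$cors$selected),
         frac_selected = mean(conn$cors$selected))

  # -- enrichment -----------------------------------------------------------
  enr <- stage("enrichment", {
    if (is.null(sim$ontology) || is.null(sim$annotations)) return(NULL)
    ann <- propagate_annotations(sim$ontology, sim$annotations)
    ppm_enr <- enrich_clusters(sig$ppm$labels, sim$ontology, ann,
                               universe = q$tensor$proteins,
                               alpha_elim = config$alpha_elim)
    write_tsv(ppm_enr, file.path(outdir, "ppm_enrichment.tsv"),
              config = cfg_plain)
    stable_enr <- NULL
    if (!is.null(core$stable$partition)) {
      stable_enr <- enrich_clusters(core$stable$partition$membership,
                                    sim$ontology, ann,
                                    universe = net$network$nodes,
                                    alpha_elim = config$alpha_elim,
                                    min_size = 5)
      write_tsv(stable_enr, file.path(outdir, "stable_enrichment.tsv"),
                config = cfg_plain)
    }
    list(ppm = ppm_enr, stable = stable_enr)
  })
  report$stages$enrichment <- if (is.null(enr)) list(skipped = TRUE) else
    list(n_ppm_tests = nrow(enr$ppm),
         n_sig_ppm_terms = sum(enr$ppm$p_adj < 0.05),
         n_stable_tests = if (is.null(enr$stable)) 0L else nrow(enr$stable))

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  log_msg(verbose, "pipeline complete; report at %s",
          file.path(outdir, "run_report.json"))
  invisible(report)
}
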