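# Synthetic-data generator: determinism, planted structure, graph simplicity,
# ontology well-formedness.

test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(n_proteins = 40, n_regions = 4, n_replicates = 3,
                    n_modules = 2, n_terms = 10, seed = 42)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$tensor$intensities, s2$tensor$intensities)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$connectome, s2$connectome)
  expect_identical(s1$annotations, s2$annotations)
  # different seed changes the data
  s3 <- simulate_all(sim_config(n_proteins = 40, n_regions = 4,
                                n_replicates = 3, n_modules = 2,
                                n_terms = 10, seed = 43))
  expect_false(identical(s1$tensor$intensities, s3$tensor$intensities))
})

test_that("zero-noise, no-effect tensor is constant across regions and replicates", {
  cfg <- sim_config(n_proteins = 15, n_regions = 4, n_replicates = 3,
                    noise_cv = 0, frac_de = 0, module_fold = 1,
                    frac_coupled = 0, couple_noise = 0, n_modules = 2,
                    n_terms = 5, seed = 7)
  ab <- simulate_abundance(cfg)
  x <- ab$tensor$intensities
  for (p in seq_len(15))
    expect_equal(max(x[p, , ]) - min(x[p, , ]), 0)
})

test_that("zero-noise planted effects give exact fold changes", {
  cfg <- sim_config(n_proteins = 30, n_regions = 4, n_replicates = 3,
                    noise_cv = 0, frac_de = 0.4, effect_fold = 2,
                    module_fold = 1, frac_coupled = 0, n_modules = 2,
                    n_terms = 5, seed = 11)
  ab <- simulate_abundance(cfg)
  mr <- region_means(ab$tensor)
  for (i in seq_len(nrow(ab$truth$de))) {
    p <- ab$truth$de$protein_id[i]
    r <- ab$truth$de$region[i]
    others <- setdiff(colnames(mr), r)
    expect_equal(unname(mr[p, r] / mr[p, others]),
                 rep(ab$truth$de$fold[i], length(others)), tolerance = 1e-12)
  }
  # non-DE proteins are flat
  flat <- setdiff(rownames(mr), c(ab$truth$de$protein_id, ab$truth$coupled))
  expect_true(all(abs(mr[flat, ] / mr[flat, 1] - 1) < 1e-12))
})

test_that("extreme SBM probabilities give disjoint cliques / empty graphs", {
  cfg <- sim_config(n_proteins = 8, n_regions = 3, n_replicates = 2,
                    n_modules = 2, ppi_p_in = 1, ppi_p_out = 0,
                    n_terms = 5, seed = 5)
  ab <- simulate_abundance(cfg)
  ed <- simulate_ppi(cfg, ab$truth)
  expect_equal(nrow(ed), 2 * choose(4, 2))   # two 4-cliques
  comm <- ab$truth$community_labels
  expect_true(all(comm[ed$protein_a] == comm[ed$protein_b]))
  # single protein: no pairs at all
  cfg1 <- sim_config(n_proteins = 1, n_regions = 3, n_replicates = 2,
                     n_modules = 1, n_terms = 5, seed = 5)
  ab1 <- simulate_abundance(cfg1)
  expect_equal(nrow(simulate_ppi(cfg1, ab1$truth)), 0)
})

test_that("PPI graphs are simple: no self-loops, no duplicates, known nodes", {
  for (seed in 1:5) {
    cfg <- sim_config(n_proteins = 30, n_regions = 3, n_replicates = 2,
                      n_modules = 3, ppi_p_in = 0.5, ppi_p_out = 0.2,
                      n_terms = 5, seed = seed)
    ab <- simulate_abundance(cfg)
    ed <- simulate_ppi(cfg, ab$truth)
    expect_true(all(ed$protein_a != ed$protein_b))
    key <- paste(pmin(ed$protein_a, ed$protein_b),
                 pmax(ed$protein_a, ed$protein_b))
    expect_equal(anyDuplicated(key), 0L)
    expect_true(all(c(ed$protein_a, ed$protein_b) %in%
                      names(ab$truth$module_labels)))
  }
})

test_that("equal in/out probabilities erase the planted density contrast", {
  # empirical within/between densities pooled over many seeds should be
  # statistically indistinguishable (two-proportion test)
  win <- c(0, 0); btw <- c(0, 0)   # successes, trials
  for (seed in 1:100) {
    cfg <- sim_config(n_proteins = 16, n_regions = 3, n_replicates = 2,
                      n_modules = 2, ppi_p_in = 0.3, ppi_p_out = 0.3,
                      n_terms = 5, seed = seed)
    ab <- simulate_abundance(cfg)
    ed <- simulate_ppi(cfg, ab$truth)
    comm <- ab$truth$module_labels
    same_tab <- table(factor(comm[ed$protein_a] == comm[ed$protein_b],
                             levels = c(TRUE, FALSE)))
    pairs <- combn(names(comm), 2)
    same_pairs <- sum(comm[pairs[1, ]] == comm[pairs[2, ]])
    win <- win + c(same_tab[["TRUE"]], same_pairs)
    btw <- btw + c(same_tab[["FALSE"]], ncol(pairs) - same_pairs)
  }
  pt <- prop.test(c(win[1], btw[1]), c(win[2], btw[2]))
  expect_gt(pt$p.value, 0.001)
})

test_that("noise-free coupled proteins track the connectivity vector exactly", {
  cfg <- sim_config(n_proteins = 20, n_regions = 5, n_replicates = 3,
                    noise_cv = 0, couple_noise = 0, frac_coupled = 0.5,
                    frac_de = 0, module_fold = 1, n_modules = 2,
                    n_terms = 5, seed = 9)
  ab <- simulate_abundance(cfg)
  cm <- simulate_connectome(cfg, ab$truth, ab$tensor)
  expect_true(all(cm >= 0))
  v <- rowMeans(cm)
  mr <- region_means(ab$tensor)
  for (p in ab$truth$coupled)
    expect_equal(abs(cor(mr[p, ], v)), 1, tolerance = 1e-9)
})

test_that("uncoupled proteins have near-zero mean |r| over many seeds", {
  rs <- c()
  for (seed in 1:100) {
    cfg <- sim_config(n_proteins = 6, n_regions = 7, n_replicates = 2,
                      noise_cv = 0.2, frac_coupled = 0, frac_de = 0,
                      module_fold = 1, n_modules = 2, n_terms = 5,
                      seed = seed)
    ab <- simulate_abundance(cfg)
    cm <- simulate_connectome(cfg, ab$truth, ab$tensor)
    v <- rowMeans(cm)
    mr <- region_means(ab$tensor)
    rs <- c(rs, suppressWarnings(cor(t(mr), v)))
  }
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.1)
})

test_that("simulated ontology is a DAG with true-path annotations recoverable", {
  cfg <- sim_config(n_proteins = 40, n_regions = 3, n_replicates = 2,
                    n_modules = 3, n_terms = 20, seed = 13)
  ab <- simulate_abundance(cfg)
  onto <- simulate_ontology(cfg, ab$truth)
  # new_ontology performs a topological sort: building it at all proves
  # acyclicity; also every non-root reaches the root
  expect_s3_class(onto$ontology, "psd_ontology")
  for (t in setdiff(onto$ontology$terms$id, onto$ontology$roots))
    expect_true(onto$ontology$roots %in% term_ancestors(onto$ontology, t))
  # planted leaf term is the most enriched term for its own module
  ann <- propagate_annotations(onto$ontology, onto$annotations)
  universe <- names(ab$truth$module_labels)
  study <- universe[ab$truth$module_labels == 2]
  ps <- vapply(onto$ontology$terms$id, function(t)
    classic_fisher(study, universe, ann$term_proteins[[t]] %||% character(0)),
    numeric(1))
  expect_equal(unname(which.min(ps)),
               which(onto$ontology$terms$id == onto$planted_terms[["2"]]))
})
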