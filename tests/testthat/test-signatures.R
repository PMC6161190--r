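# Differential stability, hierarchical clustering, module-count selection,
# Circos link construction.

ds_tensor <- function(profiles) {
  # profiles: list of region-profile vectors, one per brain, single protein
  vals <- matrix(unlist(lapply(seq_along(profiles[[1]]), function(r)
    vapply(profiles, `[`, numeric(1), r))), nrow = 1)
  make_tensor(vals, regions = paste0("R", seq_along(profiles[[1]])),
              replicates = seq_along(profiles))
}

test_that("differential stability reproduces hand-computed correlations", {
  expect_equal(differential_stability(
    ds_tensor(list(c(1, 2, 3), c(2, 4, 6))))$avg_cor, 1)
  expect_equal(differential_stability(
    ds_tensor(list(c(1, 2, 3), c(3, 2, 1))))$avg_cor, -1)
  # cov = 0.5, both sds 1 -> rho = 0.5
  expect_equal(differential_stability(
    ds_tensor(list(c(1, 2, 3), c(1, 3, 2))))$avg_cor, 0.5)
})

test_that("constant brain profiles are skipped and flagged", {
  rec <- differential_stability(
    ds_tensor(list(c(1, 2, 3), c(5, 5, 5), c(2, 4, 6))))
  expect_true(rec$flagged)
  expect_equal(rec$n_pairs, 1)         # only the non-constant pair remains
  expect_equal(rec$avg_cor, 1)
  # all pairs defined: n_pairs = choose(n_brains, 2)
  rec2 <- differential_stability(
    ds_tensor(list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))))
  expect_equal(rec2$n_pairs, 3)
  expect_true(all(rec2$avg_cor >= -1 & rec2$avg_cor <= 1))
})

test_that("DS averaging commutes with brain order and stays in [-1, 1]", {
  set.seed(30)
  cfg <- sim_config(n_proteins = 25, n_regions = 5, n_replicates = 4,
                    n_modules = 2, n_terms = 5, seed = 31)
  tensor <- simulate_abundance(cfg)$tensor
  rec <- differential_stability(tensor)
  expect_true(all(rec$avg_cor >= -1 & rec$avg_cor <= 1))
  perm <- tensor
  perm$intensities <- tensor$intensities[, , c(3, 1, 4, 2)]
  rec_p <- differential_stability(perm)
  expect_equal(rec$avg_cor, rec_p$avg_cor, tolerance = 1e-12)
})

test_that("select_high_ds honours boundary cutoffs", {
  rec <- data.frame(protein_id = c("a", "b", "c"),
                    avg_cor = c(0.9, 0.1, -0.5))
  expect_setequal(select_high_ds(rec, -1), c("a", "b", "c"))
  expect_length(select_high_ds(rec, 0.95), 0)
  expect_setequal(select_high_ds(rec, 0.1), c("a", "b"))
  # default median cutoff keeps roughly half
  expect_setequal(select_high_ds(rec), c("a", "b"))
})

test_that("consistent proteins out-rank per-brain-shuffled proteins in DS", {
  ps <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_proteins = 60, n_regions = 6, n_replicates = 5,
                      n_modules = 3, module_fold = 1.6, frac_unstable = 0.5,
                      frac_de = 0, frac_coupled = 0, noise_cv = 0.15,
                      n_terms = 5, seed = seed)
    ab <- simulate_abundance(cfg)
    rec <- differential_stability(ab$tensor)
    stable <- !(rec$protein_id %in% ab$truth$unstable)
    wilcox.test(rec$avg_cor[stable], rec$avg_cor[!stable],
                alternative = "greater")$p.value
  }, numeric(1))
  expect_lt(median(ps), 0.01)
  # and the high-DS set approximately recovers the consistent half
  cfg <- sim_config(n_proteins = 60, n_regions = 6, n_replicates = 5,
                    n_modules = 3, module_fold = 1.6, frac_unstable = 0.5,
                    frac_de = 0, frac_coupled = 0, noise_cv = 0.15,
                    n_terms = 5, seed = 99)
  ab <- simulate_abundance(cfg)
  rec <- differential_stability(ab$tensor)
  high <- select_high_ds(rec)
  consistent <- setdiff(rec$protein_id, ab$truth$unstable)
  jacc <- length(intersect(high, consistent)) /
    length(union(high, consistent))
  expect_gte(jacc, 0.9)
})

test_that("duplicated row groups split exactly at K = 2", {
  m <- rbind(matrix(rep(c(1, 5, 9, 2), 4), 4, byrow = TRUE),
             matrix(rep(c(9, 1, 2, 8), 3), 3, byrow = TRUE))
  rownames(m) <- paste0("p", 1:7)
  hc <- hierarchical_cluster(m)
  cut <- cutree(hc$row_hclust, 2)
  expect_equal(length(unique(cut[1:4])), 1)
  expect_equal(length(unique(cut[5:7])), 1)
  expect_false(cut[1] == cut[5])
})

test_that("K-cut partition is invariant to row permutation and scaling", {
  set.seed(33)
  m <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("p", 1:12), NULL))
  cut1 <- cutree(hierarchical_cluster(m)$row_hclust, 3)
  perm <- sample(12)
  cut2 <- cutree(hierarchical_cluster(m[perm, ])$row_hclust, 3)[paste0("p", 1:12)]
  # same partition up to label renaming
  expect_equal(length(unique(paste(cut1, cut2))), 3)
  cut3 <- cutree(hierarchical_cluster(m * 7)$row_hclust, 3)
  expect_equal(cut1, cut3)
})

test_that("region dendrogram groups regions sharing planted module effects", {
  hits <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_proteins = 80, n_regions = 6, n_replicates = 3,
                      n_modules = 4, module_fold = 1.8, n_shared_regions = 3,
                      frac_de = 0.05, frac_coupled = 0, noise_cv = 0.1,
                      n_terms = 5, seed = seed)
    ab <- simulate_abundance(cfg)
    mr <- region_means(ab$tensor)
    hc <- hierarchical_cluster(mr)
    # the shared regions form a clade iff every within-group cophenetic
    # distance is smaller than any distance to an outside region
    coph <- as.matrix(cophenetic(hc$col_hclust))
    shared <- ab$tensor$regions[1:3]
    other <- setdiff(ab$tensor$regions, shared)
    max(coph[shared, shared]) < min(coph[shared, other])
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("choose_k finds well-separated structure and respects forcing", {
  # three tight blobs in region space
  found <- vapply(1:20, function(seed) {
    set.seed(seed)
    centers <- matrix(rnorm(3 * 6, sd = 6), 3)
    m <- centers[rep(1:3, each = 8), ] + matrix(rnorm(24 * 6, sd = 0.4), 24)
    rownames(m) <- paste0("p", 1:24)
    as.integer(choose_k(m, 2:6))
  }, integer(1))
  expect_gte(mean(found == 3), 0.9)
  # duplicated rows: perfect separation at K = 2 with silhouette 1
  m2 <- rbind(matrix(rep(c(0, 4, 1, 3), 5), 5, byrow = TRUE),
              matrix(rep(c(5, 0, 3, 1), 5), 5, byrow = TRUE))
  rownames(m2) <- paste0("p", 1:10)
  k2 <- choose_k(m2, 2:4)
  expect_equal(as.integer(k2), 2)
  expect_equal(unname(attr(k2, "scores")["silhouette", "2"]), 1)
  # forced range
  set.seed(34)
  m3 <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("p", 1:10), NULL))
  expect_equal(as.integer(choose_k(m3, k_range = c(2, 2))), 2)
  # degenerate matrix errors
  m4 <- matrix(1, 5, 4, dimnames = list(paste0("p", 1:5), NULL))
  expect_error(choose_k(m4, 2:4), "degenerate")
})

test_that("circos links follow the counting rules and per-region sums stay <= 1", {
  # single-region protein contributes nothing
  presence <- rbind(p1 = c(TRUE, FALSE, FALSE),
                    p2 = c(TRUE, TRUE, FALSE))
  colnames(presence) <- c("A", "B", "C")
  labels <- c(p1 = 1, p2 = 1)
  links <- circos_links(labels, presence)
  expect_true(all(links$region_a != "C" | links$n_proteins == 0))
  expect_false("p1" %in% "ignored")  # p1 contributes to no link:
  expect_equal(sum(links$n_proteins), 2)  # p2 from A and from B
  # whole module positive in exactly A and B: width = size / |A positives|
  presence2 <- matrix(c(TRUE, TRUE, FALSE), 4, 3, byrow = TRUE,
                      dimnames = list(paste0("p", 1:4), c("A", "B", "C")))
  labels2 <- setNames(rep(1, 4), paste0("p", 1:4))
  l2 <- circos_links(labels2, presence2)
  ab <- l2[l2$region_a == "A" & l2$region_b == "B", ]
  expect_equal(ab$width, 4 / 4)
  # random masks: outgoing widths per region sum to <= 1
  set.seed(35)
  for (i in 1:20) {
    pres <- matrix(runif(60) < 0.5, 12, 5,
                   dimnames = list(paste0("p", 1:12), paste0("R", 1:5)))
    labs <- setNames(sample(1:3, 12, replace = TRUE), paste0("p", 1:12))
    ll <- circos_links(labs, pres)
    if (nrow(ll) == 0) next
    sums <- tapply(ll$width, ll$region_a, sum)
    expect_true(all(sums <= 1 + 1e-12))
  }
})
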