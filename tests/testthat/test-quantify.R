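# Differential abundance: normalization, transform, fold changes, tests,
# adjustment, Z-scores and the DE rules.

test_that("normalization matches median log-intensities to the reference", {
  # run with intensities {1,10,100} against reference {10,100,1000}: scalar 10
  vals <- cbind(c(10, 100, 1000), c(1, 10, 100))
  tensor <- make_tensor(vals, regions = c("A", "B"), replicates = 1)
  norm <- normalize_runs(tensor, reference = "A_1")
  expect_equal(unname(attr(norm, "scalars")["B", 1]), 10)
  expect_equal(median(log(norm$intensities[, "B", 1])),
               median(log(norm$intensities[, "A", 1])))
  # proportional run: every intensity 2x the reference -> scalar 0.5
  vals2 <- cbind(c(1, 2, 3), c(2, 4, 6))
  t2 <- normalize_runs(make_tensor(vals2, c("A", "B"), 1), "A_1")
  expect_equal(unname(attr(t2, "scalars")["B", 1]), 0.5)
  expect_equal(t2$intensities[, "B", 1], t2$intensities[, "A", 1])
  # reference run itself is unchanged (scalar 1)
  expect_equal(unname(attr(t2, "scalars")["A", 1]), 1)
})

test_that("normalization is idempotent", {
  set.seed(1)
  vals <- matrix(exp(rnorm(40, 10, 1)), 10)
  tensor <- make_tensor(vals, c("A", "B"), 1:2)
  n1 <- normalize_runs(tensor, "A_1")
  n2 <- normalize_runs(n1, "A_1")
  expect_equal(n1$intensities, n2$intensities, tolerance = 1e-12)
})

test_that("arcsinh transform has its closed-form values and is monotone", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(1), log(1 + sqrt(2)))
  set.seed(2)
  x <- sort(runif(50, 0, 1e6))
  expect_true(all(diff(arcsinh_transform(x)) > 0))
  expect_equal(arcsinh_transform(x), log(x + sqrt(x^2 + 1)))
})

test_that("fold changes are ratios of raw group means with exact inversion symmetry", {
  vals <- cbind(c(3, 1), c(3, 1), c(2, 1), c(2, 1))   # A: 3,3  B: 2,2
  tensor <- make_tensor(vals, c("A", "B"), 1:2)
  st <- group_stats(tensor)
  expect_equal(unname(st$fold["P1", "A", "B"]), 1.5)
  expect_equal(unname(st$fold["P2", "A", "B"]), 1)
  set.seed(3)
  t2 <- make_tensor(matrix(exp(rnorm(60, 8, 1)), 10), c("A", "B", "C"), 1:2)
  f <- group_stats(t2)$fold
  for (a in 1:3) for (b in 1:3)
    expect_equal(f[, a, b], 1 / f[, b, a], tolerance = 1e-12)
})

test_that("omnibus F matches the F distribution and oneway.test", {
  # groups (1,2,3) vs (4,5,6) on the already-transformed scale:
  # F = 13.5 on (1, 4) df
  x <- c(1, 2, 3, 4, 5, 6)
  p_expected <- pf(13.5, 1, 4, lower.tail = FALSE)
  expect_equal(p_expected, 0.0213, tolerance = 1e-3)
  # run through the row-wise implementation on sinh-ed values so the
  # internal ArcSinH recovers exactly these numbers
  vals <- matrix(sinh(x), 1)
  tensor <- make_tensor(vals, c("A", "B"), 1:3)
  res <- anova_and_pairwise(tensor)
  expect_equal(res$anova$F, 13.5, tolerance = 1e-9)
  expect_equal(res$anova$p, p_expected, tolerance = 1e-12)
  # independent route on random data: oneway.test with equal variances
  set.seed(4)
  vals2 <- matrix(exp(rnorm(5 * 12, 6, 0.6)), 5)
  t2 <- make_tensor(vals2, c("A", "B", "C"), 1:4)
  r2 <- anova_and_pairwise(t2)
  arc <- asinh(t2$intensities)
  for (p in 1:5) {
    dat <- data.frame(y = as.vector(arc[p, , ]),
                      g = factor(rep(c("A", "B", "C"), times = 4)))
    ow <- oneway.test(y ~ g, dat, var.equal = TRUE)
    expect_equal(r2$anova$F[p], unname(ow$statistic), tolerance = 1e-9)
    expect_equal(r2$anova$p[p], unname(ow$p.value), tolerance = 1e-9)
  }
})

test_that("pairwise Welch t matches t.test and handles identical groups", {
  set.seed(5)
  vals <- matrix(exp(rnorm(4 * 10, 6, 0.5)), 4)
  tensor <- make_tensor(vals, c("A", "B"), 1:5)
  res <- anova_and_pairwise(tensor)
  arc <- asinh(tensor$intensities)
  for (p in 1:4) {
    tt <- t.test(arc[p, "A", ], arc[p, "B", ])
    row <- res$pairwise[res$pairwise$protein_id == paste0("P", p), ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(row$p, unname(tt$p.value), tolerance = 1e-9)
  }
  # identical groups -> t = 0, p = 1
  vals_same <- cbind(c(5, 5), c(6, 6), c(5, 5), c(6, 6))
  t2 <- make_tensor(vals_same, c("A", "B"), 1:2)
  r2 <- anova_and_pairwise(t2)
  expect_true(all(r2$pairwise$t == 0))
  expect_true(all(r2$pairwise$p == 1))
  expect_true(all(r2$anova$p == 1))
  # zero within-group variance with differing means: degenerate, p = 0
  vals_deg <- cbind(c(5, 5), c(5, 5), c(6, 6), c(6, 6))
  r3 <- anova_and_pairwise(make_tensor(vals_deg, c("A", "B"), 1:2))
  expect_true(all(r3$pairwise$degenerate))
  expect_true(all(r3$pairwise$p == 0))
  expect_true(all(r3$anova$p == 0))
  # and with equal constant groups: degenerate, p = 1
  vals_flat <- cbind(c(5, 5), c(5, 5), c(5, 5), c(5, 5))
  r4 <- anova_and_pairwise(make_tensor(vals_flat, c("A", "B"), 1:2))
  expect_true(all(r4$anova$degenerate))
  expect_true(all(r4$anova$p == 1))
  expect_true(all(r4$pairwise$p == 1))
})

test_that("null omnibus p-values are uniform over replicated simulations", {
  set.seed(6)
  ps <- replicate(500, {
    vals <- matrix(exp(rnorm(9, 6, 0.4)), 1)
    res <- anova_and_pairwise(make_tensor(vals, c("A", "B", "C"), 1:3))
    res$anova$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH adjustment equals the hand step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)           # m = 1: unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_equal(order(rank(adj)), order(rank(adj)))  # monotone in ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("Z-score profiles center, scale, and flag constants", {
  expect_equal(as.vector(zscore_profile(c(1, 2, 3))), c(-1, 0, 1))
  z <- zscore_profile(c(4, 4, 4))
  expect_equal(as.vector(z), c(0, 0, 0))
  expect_true(attr(z, "flagged"))
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(sample(3:10, 1))
    z <- zscore_profile(v)
    expect_equal(sum(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("DE rules: boundary fold passes, non-significant fold fails", {
  # two proteins, regions A/B: P1 has exact 1.5-fold with tiny variance
  # (significant), P2 has 2-fold but huge within-group spread
  vals <- rbind(c(300, 300.3, 299.7, 200, 200.2, 199.8),
                c(100, 4000, 30, 20, 1000, 50))
  colnames_order <- c(1, 2, 3, 4, 5, 6)
  tensor <- make_tensor(vals[, colnames_order], c("A", "B"), 1:3,
                        peptides = c(P1 = 3L, P2 = 3L))
  q <- quantify_regions(tensor, normalize = FALSE)
  tabA <- q$de$table
  p1 <- tabA[tabA$protein_id == "P1", ]
  expect_equal(p1$fold_change, 1.5, tolerance = 1e-3)
  expect_true(p1$passes)
  expect_false(tabA[tabA$protein_id == "P2", "passes"])
  # the same P1 with a single peptide never passes
  t2 <- make_tensor(vals[, colnames_order], c("A", "B"), 1:3,
                    peptides = c(P1 = 1L, P2 = 1L))
  q2 <- quantify_regions(t2, normalize = FALSE)
  expect_false(any(q2$de$table$passes))
})

test_that("zero-noise planted DE is recovered exactly", {
  cfg <- sim_config(n_proteins = 60, n_regions = 4, n_replicates = 3,
                    noise_cv = 0, frac_de = 0.3, effect_fold = 2,
                    module_fold = 1, frac_coupled = 0, n_modules = 2,
                    n_terms = 5, seed = 21)
  ab <- simulate_abundance(cfg)
  q <- quantify_regions(ab$tensor, normalize = FALSE)
  expect_setequal(q$de$de_proteins, ab$truth$de$protein_id)
})
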