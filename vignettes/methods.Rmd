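---
title: "Regional postsynaptic proteome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional postsynaptic proteome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdregions)
```

# Scope

`psdregions` implements the analysis chain used to compare the postsynaptic
proteome across brain regions from label-free proteomic intensities: run
normalization and differential abundance, differential stability across
individual brains, co-abundance proteome modules (PPMs), abundance-weighted
protein-protein interaction (PPI) network clustering per region, extraction
of a cross-region stable core network, correlation of regional abundance
with mesoscale connectome projection volumes, and ontology enrichment with
the topology-based elimination Fisher method. Everything downstream of the
quantified intensity table is in scope; spectral acquisition, database
search and PPI database mining are not — the package starts from a
protein × run intensity table and a two-column edge list.

# Differential abundance

Each LC-MS run (one region × brain column) is rescaled by a single positive
scalar chosen so that its median log-intensity equals that of a reference
run. Intensities are then ArcSinH-transformed,
$\operatorname{asinh}(x) = \ln(x + \sqrt{x^2+1})$, which behaves like
$\ln(2x)$ for large intensities but is defined at zero and
variance-stabilizing for intensity data. Two scales deliberately coexist:

* **fold changes** are ratios of *raw* (normalized, untransformed) group
  means, so `FC(A, B) = 1 / FC(B, A)` holds exactly;
* **test statistics** (omnibus one-way ANOVA F across regions; Welch
  two-sample *t* per region pair) are computed on the *transformed* values.

The pairwise contrast procedure behind the reported "pairwise adjusted
p-values" is not fully specified by the upstream software, so the package
uses a Welch two-sample *t* on ArcSinH values per region pair — a robust
default consistent with ANOVA on transformed values — BH-adjusted across
proteins within each contrast. Rows with zero within-group variance
(possible in noise-free simulations) are flagged `degenerate` and assigned
p = 0 when group means differ and p = 1 otherwise, rather than NaN.

A protein is called differentially expressed (DE) when three rules hold
simultaneously: adjusted pairwise p < 0.05, at least 2 unique peptides, and
fold change at least 1.5 (or at most 1/1.5). The fold threshold is a
parameter: 1.5 is the default used for the region-signature analysis, with
1.3 (down 0.667) preserved as the documented alternative.

**Per-region DE sets.** The source analyses describe the fold rule once as
"compared with any other" region and count regional markers "compared with
all others". Marker-style per-region counts only make sense under the
second reading, so `de_filter(compare = "all")` is the default: a protein
belongs to region *r*'s DE set only if it passes the three rules
direction-consistently against *every* other region; the union of the
per-region sets is the headline DE count. `compare = "any"` (one qualifying
contrast suffices) is available.

# Differential stability

For each protein, its per-brain regional profile is correlated (Pearson)
between every pair of brains and the coefficients are averaged (avgCor).
All $\binom{n}{2}$ brain pairs are used — 15 for six brains. A brain with a
constant profile makes its pairs undefined; those pairs are skipped,
`n_pairs` is recorded per protein and the protein flagged. No numeric
cutoff for "high DS" is published, so the default cutoff is the median
avgCor, which structurally selects "roughly half" the proteins; it is a
config parameter.

# Proteome modules (PPMs)

Protein profiles (per-region means) are Z-scored row-wise and clustered
agglomeratively with Euclidean distance and complete linkage — the standard
heatmap defaults — and regions are clustered on the columns of the same
row-scaled matrix. The module count K is chosen by majority vote of three
internal indices evaluated on dendrogram cuts: mean silhouette width,
Calinski–Harabasz, and Dunn (ties go to the smallest K). The thirty-index
battery of the NbClust approach is deliberately not reproduced; three
complementary indices (compactness/separation, variance ratio, worst-case
ratio) are enough to vote on well-separated structure, and the count remains
overridable (`ppm_k`).

**Circos links.** A protein "positive" in more than one region links those
regions; by default positive means above the protein's geometric-mean
abundance (any presence mask can be supplied). Link width is the fraction
of the first region's positives contributing to the link. A protein
positive in $k > 2$ regions would be counted $k - 1$ times under a naive
count, letting a region's outgoing widths exceed 1; each protein's unit
contribution is therefore split equally over its $k-1$ partner links, which
preserves the "fraction of the regional proteins" reading and guarantees
per-region width sums ≤ 1.

# Weighted PPI networks and spectral clustering

The PPI graph keeps edges whose endpoints are both quantified, without
self-loops or duplicates. Edge (a, b) in region *r* gets weight
$w_r(a,b) = (\mathrm{Exp}_r(a) + \mathrm{Exp}_r(b))/2$, the mean of the
endpoints' mean abundances; topology is shared across regions, weights are
not.

Each regional graph is partitioned by recursive spectral modularity
maximization with fine-tuning:

1. For the current node group *g*, form the generalized weighted modularity
   matrix $B^{(g)}_{ij} = w_{ij} - \frac{s_i s_j}{2m} - \delta_{ij}
   \sum_{k \in g} B_{ik}$, where strengths $s$ replace degrees (the cited
   spectral method is stated for unweighted graphs; the strength-based form
   is the standard weighted generalization) and $m$ is the total edge
   weight of the whole graph.
2. Split by the sign of the leading eigenvector. Entries exactly zero go to
   group 1 (documented, stable).
3. Fine-tune with a Kernighan–Lin pass: repeatedly move the single node
   with the largest modularity gain, each node at most once per pass,
   keeping the best intermediate state; passes repeat while they improve.
4. Recurse on both halves; a group whose best split does not increase total
   Q is indivisible and becomes a community. Connected components are
   pre-split and never merged.

Numerical choices: the leading eigenpair comes from LAPACK (`eigen`) for
blocks up to 64 nodes and otherwise from a shifted power iteration
(shift = the largest absolute row sum, guaranteeing a positive-definite
operator; deterministic all-ones-plus-index-ramp start vector; tolerance
1e-10; LAPACK fallback if 2000 iterations do not converge). There is no
randomness anywhere, so identical inputs give identical partitions.
Weights are internally rescaled to mean 1 — modularity is invariant to
weight scale — so the improvement tolerances (1e-10 × total weight) are
meaningful whether weights are raw intensities (~10^6) or unit.

Modularity is the weighted Newman–Girvan
$Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \frac{s_i s_j}{2m}\right)
\delta(c_i, c_j)$; the implementation is verified in the tests against a
literal double-sum oracle and, on exhaustively enumerable graphs (≤ 8
nodes, all set partitions), against the global optimum, where the
spectral + fine-tuning heuristic is required to attain the optimum in at
least 90% of random instances — it is a heuristic, and the tests treat it
as one.

# Stable core network

For every edge and every region, the edge scores 1 if its endpoints fall in
different communities of that region's partition and 0 otherwise; scores
sum over regions (0 = always co-clustered, R = never). Only within-region
co-membership enters, so no label alignment across regions is needed. The
stable network keeps edges with score ≤ 2 — with seven regions, co-clustered
in at least 5/7 of the regional networks — and is re-clustered with the same
spectral method, weighted by the across-region mean abundance (the source
does not state the re-clustering weights; this keeps the weighting rule
uniform). For other region counts the ≤ 2 rule generalizes as roughly
`ceil(2R/7)`, left to configuration. Stable clusters are compared with the
PPMs by one-sided hypergeometric tests, BH-adjusted across all
cluster × module pairs.

An undefined upstream "robustness" edge-weighting procedure is referenced
but never specified in the source material; it is not invented here —
`spectral_partition()` accepts arbitrary per-edge weights instead.

# Connectome correlation

The connectivity vector is the row mean of the region × region
projection-volume matrix, diagonal included (self-projection is part of the
mean, as literally specified). Each protein's per-region mean abundance is
correlated with this global vector; r, r², and the Fisher transform
z = atanh(r) (r clipped at 1 − 1e-12) are reported, and proteins with
r² ≥ 0.6 are selected. Whether correlation should use one global vector or
per-source-region vectors is ambiguous in the source; the global vector is
the default, and `correlation_cluster()` computes the per-source-region
protein × region correlation matrix (the heatmap-style view) as the
explicit alternative. Constant protein profiles are flagged and never
selected; a constant connectivity vector is an error.

# Enrichment

Annotations are propagated up the is-a DAG (true-path rule) before testing.
Classic enrichment of a study set is the one-sided hypergeometric upper
tail $P(X \ge k)$. The elimination Fisher algorithm processes terms
bottom-up (children strictly before parents; level = longest path to a
root; lexicographic term-id order within a level, deterministic): when a
term's p-value falls below `alpha_elim` (default 0.01, the conventional
elimination threshold), the proteins currently annotated to it are removed
from all its ancestors' annotation sets before the ancestors are tested.
Classic and elimination p-values are both reported. The universe is
explicit everywhere: the network node set for network-cluster enrichment
and the full quantified proteome for PPM/DE enrichment, both configurable,
since the original universe choice is unstated.

# The synthetic-data generator

`simulate_all()` generates every pipeline input with planted ground truth:

* **Abundance tensor** — `intensity(p, r, k) = baseline(p) ·
  moduleEffect(module(p), r) · deEffect(p, r) · exp(ε)`. Baselines are
  log-normal (meanlog 13.8, sdlog 1.5, giving realistic 10^5–10^7 summed
  peptide intensities); noise is multiplicative log-normal with
  sd = log(1 + noise_cv), since summed intensities are positive and
  right-skewed, matching the ArcSinH/log treatment of the real data. The
  defaults emulate the study scale: 1173 proteins × 7 regions × 6 brains,
  six modules, 30% planted DE at fold 2 in one region each (up or down),
  noise CV 0.1.
* **Module effects** are kept small by default (`module_fold` 1.15, below
  the 1.5 DE threshold) so co-abundance structure does not masquerade as
  planted DE; the first `n_shared_regions` (3) regions share a correlated
  effect component, emulating anatomically related ("cortex-like") regions.
* **Peptide counts** default to ≥ 2 for every protein because the emulated
  dataset was itself pre-filtered to two unique peptides; a configurable
  single-peptide fraction exercises the peptide filter.
* **PPI graph** — planted-partition (SBM-like) graph aligned to the
  modules; defaults p_in 0.05 / p_out 0.004 yield roughly 8000 interactions
  over ~1000 connected proteins, matching the scale of a mined PPI network.
* **Connectome** — a latent positive regional profile g is drawn
  (`couple_fold` 1.5); a `frac_coupled` (10%) subset of proteins follows g
  instead of its module effect, and the connectome matrix is built so its
  row means equal an affine function of g (times optional entry noise), so
  noise-free coupled proteins correlate perfectly with the connectivity
  vector by construction.
* **Ontology** — a three-layer is-a DAG (root, branches, leaves; some
  leaves with two parents) in which one leaf per module is annotated with
  80% of that module's proteins and remaining leaves carry random
  background annotations.

One global seed is split into fixed per-component substreams, so
regenerating one component never reshuffles the others, and identical
configurations are bit-identical.

**What the generator does not emulate:** missing values and
limit-of-detection censoring, peptide-level structure, correlated
(batch-like) noise, heavy-tailed contamination, scale-free PPI degree
distributions, and literature-bias in annotations. Passing the recovery
tests therefore demonstrates correctness of the algorithms under the
planted model, not robustness to every artefact of real LC-MS data.

**Recovery-test conditions.** The planted DE map is a complete ground truth
only when the other planted mechanisms are silent, so the DE-recovery check
runs the generator with `module_fold = 1` and `frac_coupled = 0` at the
stated conditions (fold 2, noise CV 0.1, 6 replicates, 7 regions, 1000
proteins). Likewise, the differential-stability check plants
`frac_unstable = 0.5` (half the proteins re-permuted per brain) and the
community-recovery check uses 4 blocks × 20 nodes at p_in 0.9 / p_out 0.05.
Exhaustive modularity optima are verified on graphs of 5–8 nodes (all set
partitions enumerated); the brute-force modularity oracle runs on graphs up
to 50 nodes. These problem sizes are the package's test design, chosen so
each property is checked at the scale where its oracle is exact.

# Worked example

```{r example, eval = FALSE}
library(psdregions)
cfg <- run_config()            # study-scale synthetic defaults
report <- run_pipeline(cfg, outdir = "psd_run", seed = 1)
report$stages$quantify$frac_de        # fraction of DE proteins
report$stages$network$Q               # modularity per region
report$stages$core$stable_fraction    # stable interaction fraction
```

The run directory contains the simulated inputs plus per-stage outputs: the
DE and DS tables, PPM assignment and Newick dendrograms, Circos karyotype
and link files, per-region partitions and GEXF exports, stability scores
and the stable network, connectome correlations, and enrichment tables;
`run_report.json` summarizes every stage and contains no timestamps, so
identical seeds give byte-identical reports.

# Known limitations

* The spectral + Kernighan–Lin procedure is a heuristic; it can miss the
  global modularity optimum (observed on < 10% of small random graphs) and
  its community count depends on the weight structure.
* Welch-t pairwise contrasts are a stated interpretation of an
  under-specified upstream procedure, as is the "all others" regional
  marker rule; both are switchable.
* The elimination algorithm is order-dependent by design (bottom-up,
  deterministic tie-breaks); other topology-aware schemes (weight-based,
  parent-child union) are out of scope.
* The DS statistic uses all 15 brain pairs; the source text mentions 14
  without explanation, and `n_pairs` is recorded per protein so any
  subsetting convention can be audited.
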