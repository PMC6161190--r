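# psdregions

Analysis of regional diversity in the postsynaptic proteome. The package
implements, as reusable R functions with a synthetic-data generator for
testing, the analysis chain used to compare label-free proteomic
quantifications of postsynaptic density (PSD) proteins across brain regions
and individual brains:

1. **Differential abundance** — median-matching run normalization, ArcSinH
   transform `asinh(x) = ln(x + √(x²+1))`, fold changes on raw group means,
   one-way ANOVA and pairwise Welch *t* on transformed values,
   Benjamini–Hochberg adjustment, and the three-rule DE call
   (adjusted p < 0.05, ≥ 2 unique peptides, fold ≥ 1.5 or ≤ 1/1.5).
2. **Differential stability (DS)** — per protein, the average pairwise
   Pearson correlation of its regional profile across individual brains
   (avgCor); high DS = reproducible regional pattern.
3. **Proteome modules (PPMs)** — hierarchical clustering (Euclidean,
   complete linkage, row Z-scores) of the protein × region matrix, with the
   module count chosen by majority vote of silhouette, Calinski–Harabasz
   and Dunn indices; Circos karyotype/link files for inter-region module
   sharing.
4. **Weighted PPI networks** — per-region edge weights
   `w_r(a,b) = mean(Exp_r(a), Exp_r(b))`, clustered by recursive spectral
   modularity maximization (leading eigenvector of the generalized
   strength-weighted modularity matrix) with Kernighan–Lin fine-tuning,
   maximizing `Q = (1/2m) Σ_ij (w_ij − s_i s_j / 2m) δ(c_i, c_j)`.
5. **Stable core network** — each interaction scores, over regions, an
   indicator of its endpoints being split across communities; edges with
   score ≤ 2 (co-clustered in ≥ 5/7 regional networks) form the stable
   network, re-clustered and compared with PPMs by hypergeometric overlap.
6. **Connectome correlation** — Pearson r between per-region mean abundance
   and the connectivity vector (row mean of the projection-volume matrix,
   diagonal included), with Fisher z and an r² ≥ 0.6 selection rule.
7. **Enrichment** — true-path annotation propagation over an is-a ontology
   DAG, classic one-sided hypergeometric tests, and the topology-based
   elimination Fisher algorithm (genes of significant child terms are
   removed from ancestors before those are tested).

Every stage is exercised end-to-end on a synthetic-data generator that
plants known ground truth (DE effects, co-abundance modules, SBM-like PPI
communities, connectome-coupled proteins, module-annotated ontology terms),
so the whole pipeline is testable without external data. See
`vignettes/methods.Rmd` for the models, parameter choices and limitations.

## Worked example

```r
library(psdregions)
report <- run_pipeline(run_config(), outdir = "psd_run", seed = 1)
```

`run_config()` defaults to the study-scale synthetic conditions
(1173 proteins × 7 regions × 6 brains, ~8000 PPI edges). The run takes
about a minute and prints per-stage progress; `report` (also written as
`psd_run/run_report.json`) contains, for seed 1:

| quantity | value | meaning |
|---|---|---|
| `quantify$n_de` | 294 (25.1%) | proteins passing all three DE rules against every other region |
| `signatures$ppm_k` | 8 | proteome-module count chosen by the index vote |
| `signatures$ds_range` | 0.10 – 0.99 | differential-stability (avgCor) range; 587 proteins above the median cutoff |
| `network$Q` | 0.54 – 0.55 | modularity of the 7 regional weighted PPI partitions (10–12 communities each) |
| `core$stable_fraction` | 0.544 | fraction of the 7959 interactions co-clustered in ≥ 5/7 regions |
| `connectome$frac_selected` | 0.134 | proteins with r² ≥ 0.6 against the connectivity vector (10% were planted as coupled) |

The run directory additionally holds the simulated inputs, DE/DS tables,
PPM assignments, Newick dendrograms, Circos files, per-region partitions,
GEXF graph exports, stability scores, the stable network, connectome
correlations and enrichment tables. A thin CLI wrapper is installed under
`exec/psdregions` (subcommands `simulate`, `run`, `quantify`, `signatures`,
`network`, `core`, `connectome`, `enrich`).

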