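# iegnet

Functional connectivity networks from regional immediate early gene (IEG)
expression densities.

## The problem

Brain-wide activity mapping with IEGs such as *c-Fos* measures, for every
brain region, the density of activity-tagged cells in each animal of a
cohort. Because each brain is sampled once, functional connectivity cannot be
estimated from a time series as in fMRI; instead, the density of each pair of
regions is correlated **across animals**. Region pairs whose activity
co-fluctuates across the cohort are declared functionally connected, the
supra-threshold correlations are binarized into a network, and the network is
characterized with graph theory.

`iegnet` implements that pipeline for experimentalists and analysts working
with region-by-animal density tables, together with the two robustness
analyses that matter most in practice: how the network degrades with **group
size**, and how sensitive its topology is to the **binarization threshold**.
A synthetic-cohort generator with a known ground-truth network makes every
stage testable without any animal data.

## The model

Given a table `x[i, a]` of densities (region `i`, animal `a`, in labels/µm²;
[`cavalieri_density()`] converts raw counts using the grid-point area
estimate `grid_points × spacing²`):

- **Correlation.** For every region pair, the Pearson coefficient
  `r_ij = cor(x[i, ], x[j, ])` across the `n` animals, with the two-tailed
  p-value from the exact t-transform
  `t = r√(n−2)/√(1−r²) ~ t(n−2)`.
- **Thresholding.** Edge `(i, j)` exists iff `p_ij ≤ α`, optionally the pair
  survives Benjamini–Hochberg FDR at rate `q` over the family of all
  `C(N,2)` pairs, optionally `|r_ij| ≥ r_min`, and the sign policy admits it
  (`positive_only` drops anticorrelations — the common practice — while
  `absolute` and `signed` keep them as an explicit choice).
- **Graph metrics.** Degree, network density `2E/(N(N−1))`, global
  efficiency (mean inverse geodesic distance; 0 for disconnected pairs),
  local clustering, Latora–Marchiori local efficiency, normalized
  betweenness, characteristic path length, and the small-world coefficient
  `σ = (C/C_rand)/(L/L_rand)` against Erdős–Rényi or degree-preserving null
  ensembles.
- **Stability.** For every subgroup size `k` the scan recomputes the network
  on **all** `C(n,k)` animal subsets and reports, per edge, the fraction of
  subsamples whose significance verdict flips relative to the full cohort
  (false-negative-type for full-cohort-significant edges,
  false-positive-type otherwise) and the variance of the p-value across
  subsamples.
- **Synthetic cohorts.** A ground-truth binary network induces a target
  correlation matrix `I + r·A` (projected to the nearest positive-definite
  correlation matrix when needed); animals are multivariate-Gaussian draws
  mapped to non-negative densities via a softplus transform.

## Worked example

```r
library(iegnet)

# a 60-region, 12-animal cohort with known structure
truth  <- make_ground_truth(n_regions = 60, edge_density = 0.1, seed = 7, effect_r = 0.7)
cohort <- simulate_cohort(truth, cohort_spec(n_animals = 12), seed = 11)

corr <- correlate_table(cohort)
net  <- binarize(corr, threshold_spec(alpha = 0.05))
net
#> <fc_network> 60 regions, 94 edges (density 0.053)

network_metrics(net, sigma = TRUE, seed = 3)
#> <metrics_report> 60 regions
#>   density 0.053 | global efficiency 0.225 | mean clustering 0.256
#>   char path length 3.901 over largest component covering 82% of regions
#>   small-world sigma 3.493

scan <- subsample_scan(cohort, sizes = 3:11, spec = threshold_spec(alpha = 0.05))
scan
#> <stability_report> 1770 edges x sizes 3..11 (4016 subsample networks, exhaustive)
#>   mean p-variance by size: k3=0.0813 k4=0.0778 k5=0.0737 k6=0.0688 k7=0.0628
#>   k8=0.0556 k9=0.0466 k10=0.0355 k11=0.0221
```

The network is far denser than the 5% a pure null would give (true edges plus
chance), shows strongly small-world topology (σ ≈ 3.5), and the stability
scan reproduces the core group-size phenomenon: the mean per-edge p-value
variance falls monotonically as the subgroup grows from 3 toward the full
cohort, i.e. small groups give statistically unpredictable networks. The
t-transform also reproduces published cohort statistics directly:

```r
round(p_two_tailed(c(0.6193, 0.2539), 12), 4)
#> [1] 0.0318 0.4259
```

Real data enter through `load_region_table("densities.csv")` (first column
`region`, one column per animal) or `density_from_counts()` for raw
count + grid-point tables; `run_pipeline()` chains
ingest → correlate → threshold → metrics (→ stability) and writes all
artifacts — labelled CSV matrices, edge-list TSV, GraphML, JSON metrics — plus
a provenance sidecar that reproduces the run bit-exactly. A thin CLI with the
same stages is in `exec/iegnet`.

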