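---
title: "Methods: IEG-based functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IEG-based functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iegnet)
```

## The estimand and its assumptions

Immediate early gene (IEG) mapping gives one brain per animal, so
"functional connectivity" here is a *group-level* statistic: the Pearson
correlation, across the animals of a cohort, between the activity densities
of two regions. The pipeline therefore assumes

- densities are comparable across animals (same tagging window, staining and
  segmentation protocol — upstream concerns outside this package's scope);
- the cohort is homogeneous enough that a single correlation per region pair
  is meaningful;
- an approximately linear, bivariate-normal dependence between region pairs,
  which is what Pearson's r and its t-transform p-value assume. With a
  cohort of ~12 animals there is no power to verify this per pair, which is
  exactly why the group-size diagnostics exist.

p-values use the exact transform `t = r·sqrt(n−2)/sqrt(1−r²)` on `n−2`
degrees of freedom, two-tailed. At `n = 12` this reproduces published cohort
values (`p_two_tailed(0.6193, 12)` ≈ 0.0318, `p_two_tailed(0.2539, 12)` ≈
0.4258), which is the evidence that published analyses of this kind use the
same transform rather than a permutation scheme.

## Thresholding parameters

`threshold_spec()` collects every binarization decision so none is silent:

- `alpha` (default 0.05; conventional alternatives 0.005, 0.0005). The
  comparison is `p ≤ alpha`. Since topology is threshold-sensitive, results
  should be reported at several levels; stricter levels always give nested
  edge sets, a structural fact the tests verify.
- `fdr_q` (optional, conventionally 0.05): Benjamini–Hochberg step-up over
  the family of **all unique region pairs of the current node set** (1770
  for 60 regions), per network. The package does not make the FDR decision
  for you; with a 12-animal cohort and 1770 pairs the BH threshold is severe
  and can empty a synthetic network whose true correlations are moderate,
  whereas real cohorts — whose correlation distribution is heavy with strong
  positive values — retain edges. Both raw-alpha and FDR-filtered modes are
  first-class, and provenance records which was used.
- `r_min` (optional): a critical-value floor on `|r|`, for workflows that
  threshold on the coefficient rather than (or in addition to) its p-value.
- `sign_policy`: `positive_only` (default, the field's common exclusion of
  anticorrelations), `absolute`, or `signed`. The default is deliberately
  visible and reversible because the exclusion is debated; `signed` keeps
  the sign on each edge for downstream use.

Zero-variance regions (constant across the cohort — possible in synthetic or
degenerate data, not observed in practice) have undefined correlations; every
pair involving one is assigned `r = 0, p = 1` with a warning, so such a
region can never gain an edge and a long batch run never aborts midway.

## Graph measures

Degree, density, global efficiency, local clustering, local efficiency and
normalized betweenness are computed on the binary, symmetric, hollow
adjacency matrix (igraph backs the computations; brute-force oracles verify
every measure in the test suite). Conventions worth stating:

- **Local efficiency** follows Latora–Marchiori: the global efficiency of
  the subgraph induced by a node's neighbors, with paths confined to that
  subgraph. Some toolboxes let neighbor-to-neighbor paths traverse the rest
  of the graph, which yields systematically larger values; the confined
  definition is implemented explicitly here.
- **Clustering and local efficiency for degree < 2 are 0**, not dropped, so
  per-region vectors stay alignable across thresholds.
- **Characteristic path length** is the mean geodesic over connected pairs
  only; `component_coverage` (fraction of regions in the largest connected
  component) is always reported beside it so a path length over a fragment
  is never mistaken for one over the whole network. Efficiency-based
  measures, which handle disconnection natively (1/∞ = 0), are preferred for
  cross-threshold comparison.
- **Betweenness** is normalized by `(N−1)(N−2)/2`. "Centrality" in this
  literature is generic; betweenness is implemented as the canonical choice.
- **Small-world σ** compares mean clustering and characteristic path length
  on the largest component against a null ensemble: `er_matched` (G(N, E)
  with matched node and edge counts) or `degree_preserving` (Maslov–Sneppen
  rewiring; 10·E rewiring trials per null by default, configurable). A null
  ensemble with zero mean clustering raises an explicit undefined-σ error
  rather than dividing by zero. The ensemble is seeded and bit-reproducible.

## The synthetic cohort generator

The generator exists because no public region-by-animal dataset accompanies
analyses of this kind, and because calibration and recovery claims need a
known truth. Its construction:

1. `make_ground_truth(n_regions, edge_density, seed, effect_r)` samples a
   binary symmetric hollow adjacency with
   `round(edge_density · C(n_regions, 2))` edges uniformly at random.
2. `target_correlation_matrix()` forms `I + effect_r·A`. When that matrix is
   indefinite (any node of degree ≥ 2 at strong effect sizes), it is
   replaced by the **nearest positive-definite correlation matrix**
   (Higham's alternating projections, `Matrix::nearPD`). The projection is
   reported via the `projected` and `max_shift` attributes: at 60 regions,
   10% density and `effect_r = 0.7`, on-edge correlations shrink to roughly
   0.3–0.65 and off-edge entries acquire magnitudes mostly below 0.2. All
   recovery guarantees are stated against the *projected* matrix, which is
   the actual sampling distribution.
3. `simulate_cohort()` draws animals i.i.d. from `N(0, R)`, scales by
   `noise_sd`, shifts by `baseline`, and maps to non-negative densities with
   a **softplus** transform by default (smooth and nearly linear around the
   default baseline of 5, so Pearson correlations are essentially
   preserved). `exponential` gives log-normal-like skew; `none` keeps the
   exact multivariate Gaussian and is the right choice for calibration
   checks of the t-transform (with a baseline far from 0 the values remain
   positive in practice). `baseline = 5`, `noise_sd = 1` are arbitrary but
   harmless defaults: Pearson r is location/scale invariant, so they shape
   only the marginal scale, not the network.
4. Optional **outlier injection** replaces an animal's latent vector with
   `baseline + magnitude · noise_sd · u` for a random unit direction `u` —
   the simplest mechanism that reproduces the known vulnerability of
   small-cohort correlations to a single aberrant animal.

Structure and sampling take separate seeds, so one truth can back many
cohorts. What the generator deliberately does **not** emulate: spatial or
image-level structure, segmentation/registration error, inter-regional
baseline heterogeneity (settable but not defaulted), heavy-tailed biological
variability, or animal-level covariates. Passing recovery tests on this
generator therefore shows the *pipeline* is correct and calibrated under its
stated model — not that any particular real dataset satisfies that model.

## The group-size stability scan

`subsample_scan()` recomputes the correlation matrix for **every** subset of
animals at each requested subgroup size k (exhaustive, `C(n,k)` subsets;
sizes below 3 are refused since the p-value needs 3 points). Per edge and
size it reports

- the **flip rate**: the fraction of subsamples whose significance verdict
  differs from the full-cohort verdict. Edges significant at full cohort
  flip toward false negatives; nonsignificant edges toward false positives.
  The full-cohort verdict is the reference — no external truth is assumed
  for real data (for synthetic data the ground truth is available
  separately).
- the **p-value variance** across same-size subsamples (of the raw p; a
  transform hook would be easy but raw p is what the per-size aggregate
  summarizes). The per-size aggregate is the mean over edges by default,
  with median as an option.

The significance verdict inside each subsample uses the same
`threshold_spec` as the full cohort, and when FDR is configured the BH
family is re-applied *within* each subsample — the self-consistent choice.
For the flip-rate phenomenology itself the raw `alpha = 0.05` verdict is the
informative mode at n = 12 (see the FDR note above).

`select_median_variance_network()` scores each size-k subsample by the
variance of its p-value distribution over all region pairs, ranks the
combinations, and rebuilds the median-ranked one (lower median for even
counts; ties broken by lexicographic combination order, with a message).
This gives a principled "representative small-group network" to set against
the full-cohort network, and on study-scale synthetic cohorts its degree
distribution differs clearly from the full network's — the small-sample
distortion the scan is designed to expose.

For cohorts above 14 animals the exact enumeration explodes combinatorially
and a seeded Monte-Carlo subset (capped per size) replaces it, flagged in
the report. At the study scale this package targets (12 animals, 60 regions,
sizes 3–11, 4016 networks) the exhaustive scan runs in a few seconds.

## Problem sizes used by the tests

The suite checks oracle equivalence on 200 random graphs of up to 12 nodes
and 1000 random p-vectors; calibration on 200 null cohorts of 60 regions ×
12 animals (354,000 null pairs, observed type-I ≈ 0.050 at α = 0.05);
false-discovery control on 100 cohorts at n = 30 where BH has power
(mean FDP ≈ 0.05 against ground truth); and edge recovery at n = 100 with
`effect_r = 0.7` (sensitivity and specificity above 0.9 against the
projected target). These sizes were chosen as the smallest at which the
respective statistical claims are measurable with comfortable margins.

## Known limitations

- Pairwise Pearson correlation cannot distinguish direct coupling from
  shared drive; no partial-correlation or latent-factor mode is offered.
- Weighted-network analysis is out of scope; matrices are binarized.
- Missing cells are rejected, not imputed: correlation-across-animals has no
  defined behavior for missing data, and pairwise-complete correlation
  silently changes the n per pair, so it is deliberately not offered.
- The t-transform p-value is exact only under bivariate normality; with
  12 animals, departures are undetectable per pair. The stability scan is
  the package's answer to that uncertainty: it measures how fragile each
  verdict actually is under resampling of the cohort itself.
- Grid-point counts for the Cavalieri density are treated as already summed
  per region across sections; per-section bookkeeping is upstream.
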