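---
title: "Estimating the number of clusters as a multi-criteria decision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of clusters as a multi-criteria decision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdmk)
```

## The model

No single internal validity index reliably identifies the number of
clusters across data sets: indices encode different notions of
compactness and separation, and they disagree. `mcdmk` therefore frames
the choice of k as a multi-criteria decision problem. The candidate
cluster counts are the alternatives; the scores of a k-means partition
at each candidate on ten relative validity indices are the criteria;
and three MCDM methods — the weighted sum model (WSM), PROMETHEE II and
TOPSIS — aggregate the criteria into complete rankings of the
candidates. The rank-1 alternative of each method is its recommended k.

The approach assumes only that (a) the clustering algorithm can produce
a reasonable partition at the true k, and (b) a plurality of the
weighted criteria favour the true k more than any other candidate. It
does not assume the indices agree, which is the point: a candidate that
is merely second-best on many criteria can beat one that is best on a
single idiosyncratic criterion.

## The criteria and their directions

Dunn, silhouette and PBM are benefit criteria (larger is better);
Hubert Γ, normalized Hubert Γ, Davies–Bouldin, SD, S_Dbw, CS and
C-index are treated as cost criteria (smaller is better). Treating the
two Hubert statistics as cost criteria is a deliberate convention of
the estimator rather than a universal one — normalized Γ is elsewhere
often maximized — so `criterion_directions` is exported and every
ranker accepts a decision matrix whose `directions` field has been
overridden, should a user prefer the opposite reading.

Implementation notes per index (all distances Euclidean; the proximity
matrix is computed once per data set and shared across all ten
indices):

* **Hubert Γ** uses cluster centroids as the representative points, so
  co-clustered pairs contribute zero; the normalized form is the
  Pearson correlation between the pairwise-distance vector and the
  centroid-distance vector.
* **SD** is `α·Scat(k) + Dis(k)` with population (divide-by-n)
  variance vectors inside `Scat`. The weight `α = Dis(c_max)` is
  evaluated at the largest k of the sweep, making the SD column
  sweep-dependent by construction; a standalone `sd_index()` call
  defaults to `α = Dis(k)` of the solution it is given.
* **S_Dbw** uses the neighbourhood radius
  `stdev = (1/k)·sqrt(Σ_i ||σ(C_i)||)` and compares midpoint density to
  the denser of the two cluster centers.
* **Silhouette** assigns `s(i) = 0` to members of singleton clusters,
  the standard convention.
* **C-index** compares the within-cluster distance sum against the
  sums of the `l` smallest and largest of all pairwise distances.

## Degenerate evaluations

Indices can be undefined on pathological partitions: coincident
centroids (Davies–Bouldin, SD, CS denominators), all-zero cluster
diameters (Dunn's own limit is +∞), constant distance structure
(normalized Γ, C-index), empty center neighbourhoods (S_Dbw). Index
functions surface these as `NaN`/`Inf` rather than guessing. When the
sweep's decision matrix is assembled, a degenerate entry is replaced by
the worst finite value its criterion attained across the sweep, pushed
10% of the column range further in the unfavourable direction, and the
replacement is flagged. This keeps the matrix finite — the MCDM methods
require that — without silently rewarding a degenerate partition. A
criterion degenerate at every k aborts with a diagnostic naming it.
Per-index best-k reports (`best_k_per_index()`) use the raw values, so
an infinite Dunn value still counts as that index's optimum, and exact
ties are reported as the full tied set.

## Clustering

The partitions come from a Lloyd k-means minimizing the within-cluster
sum of squared errors. Initial centers are k distinct rows drawn
uniformly at random — the simplest textbook initialization — with
k-means++ available behind `init = "plusplus"`. Each k keeps the best
of `restarts` runs (default 10) by WCSS; restart r of seed s uses seed
s + r − 1, so the whole sweep is reproducible from one integer.
Iteration stops when no centroid moves more than `tol` (default 1e-6)
or after `max_iter` (default 100). A cluster that empties mid-run is
reseeded with the point farthest from its assigned center, preserving
the "exactly k clusters" semantics that the validity indices assume.
Features are not standardized by default; `standardize = TRUE` applies
z-scoring when attributes are on incommensurable scales. The pipeline
also accepts precomputed partitions (`partitions =`), so any clustering
algorithm's output can be ranked identically.

## The rankers

* **WSM** needs commensurable criteria, and raw index magnitudes differ
  by orders of magnitude (Hubert Γ can be in the hundreds while
  silhouette is in [−1, 1]); each column is therefore min–max scaled to
  [0, 1] across alternatives before the benefit-minus-cost weighted
  sum. Raw-scale aggregation remains available (`scale = "raw"`) for
  data whose criteria are already comparable; without scaling,
  large-magnitude criteria dominate silently, which is why scaling is
  the default.
* **PROMETHEE II** uses only the usual (parameter-free) preference
  function: criterion j prefers a over b exactly when a strictly beats
  b on j after direction adjustment. The five parameterized preference
  function families are not implemented, so no indifference/preference
  thresholds exist anywhere in the interface.
* **TOPSIS** vector-normalizes columns, which presumes nonnegative
  entries; a column containing negatives (silhouette or normalized Γ
  can be negative) is shifted by its minimum first, a standard TOPSIS
  practice.
* Exact score ties are broken toward the smaller k (parsimony), making
  reports deterministic. Near-ties among the top three alternatives —
  score gaps below 0.01 by default — are flagged and always reported
  with their scores, since a ranking order alone overstates the
  confidence of a 0.002 difference.
* Weights default to uniform (1/10 each). When domain experts are
  available, a matrix of 0–10 importance scores (one row per expert) is
  averaged per criterion and normalized to sum to one
  (`normalize_expert_weights()`); weight files in either form are
  auto-detected by `read_weight_file()`.

## The synthetic benchmark generator

`generate_mixture()` draws isotropic Gaussian mixtures with a
guaranteed minimum center separation: centers sit on a grid scaled to
the requested separation plus the maximal jitter, then are jittered, so
the separation invariant holds deterministically rather than by
rejection. This emulates the one property the estimator's correctness
argument needs — a data set with an unambiguous true k — with
controllable difficulty (separation in units of σ). It does not emulate
unequal cluster shapes, correlated attributes, outliers, or categorical
noise, all common in real benchmarks; passing the synthetic recovery
test therefore demonstrates that the pipeline aggregates correctly when
structure is present, not that k-means plus these indices resolve
overlapping or non-spherical clusters. The bundled estimates from a
fifteen-dataset UCI benchmark study (`benchmark_estimates()`) exercise
the reporting logic on real-data results instead.

## Problem sizes and verification

The test suite verifies each index against an independent naive-loop
oracle (tolerance 1e-9) on 100 random instances with n ≤ 30 and k ≤ 5,
checks the k-means objective against exhaustive partition enumeration
for n ≤ 8, and checks ranking invariants (Σφ = 0, φ ∈ [−1, 1],
C\* ∈ [0, 1], dominance consistency, criterion-permutation equivariance,
single-criterion agreement) on 1,000 random decision matrices. The
end-to-end recovery property uses twenty mixtures of four 2-D Gaussian
clusters, 50 points each (n = 200), at separation 10σ — comfortably
separated but not trivial, a regime where a practitioner would expect
any sensible estimator to succeed — and requires all three methods to
recommend k = 4 in at least 90% of runs. A four-point 1-D fixture with
hand-derived values for seven indices anchors the arithmetic
end-to-end.

## Known limitations

* Quadratic memory in n for the proximity matrix; data sets beyond a
  few tens of thousands of rows need subsampling.
* The estimator inherits k-means' bias toward spherical, equally sized
  clusters; injected partitions from another algorithm mitigate this.
* Only crisp partitions are scored; fuzzy validity indices are out of
  scope.
* Weight elicitation quality is the user's responsibility; the package
  only consumes score files and offers no sensitivity analysis of the
  weights.
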