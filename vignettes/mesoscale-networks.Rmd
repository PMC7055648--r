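---
title: "Mesoscale functional networks from single-cell calcium imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale functional networks from single-cell calcium imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mesoconn` reconstructs and analyses whole-brain mesoscale functional
connectivity (FC) from multi-subject single-cell calcium fluorescence
recordings of the kind produced by light-sheet imaging of larval zebrafish:
tens of thousands of segmented cells per subject, aligned across subjects,
imaged at about two volumes per second under spontaneous and visual-stimulus
conditions. The package covers the full analysis chain — cell-to-parcel
definition, signed network construction with surrogate nulls, hierarchical
and multilayer community detection, hub and flexibility metrics, and
geometry/similarity analyses — together with a synthetic-data generator with
planted ground truth, so every stage is testable without any download.
Acquisition, segmentation, and anatomical registration are assumed done
upstream.

# Network construction

Cells are aggregated into *parcels* (network nodes) that are spatially
contiguous, functionally homogeneous, hemispherically symmetric, and shared
across subjects. For each subject and condition, the parcel trace is the
mean fluorescence of its member cells, and the network is the matrix of
Fisher-transformed Pearson correlations between parcel traces,

$$A_{ij} = \mathrm{atanh}\, r_{ij},$$

a fully weighted, signed matrix with zero diagonal. Correlations at $\pm 1$
are clipped to $\pm(1 - 10^{-12})$ before the transform. Per-condition
networks use globally regressed traces (regression on the concatenation of
all conditions) restricted to that condition's frames; group networks are
element-wise means across subjects.

To confirm that FC is not driven by low-level trace statistics, we build
phase-randomized surrogates: each trace's discrete Fourier transform
receives independent uniform phase offsets on the positive-frequency bins
(conjugate-symmetric mirror; DC and Nyquist untouched), and is inverted.
This preserves each amplitude spectrum — hence mean and variance — exactly
while destroying cross-correlations. Surrogate-to-source network similarity
is measured with Spearman correlation of upper-triangle weights and should
be near zero.

# Parcellation

The multistage procedure:

1. **Spatial clustering.** k-means (Euclidean, best of `n_replicates` by
   within-cluster sum of squares) on left-hemisphere cell coordinates pooled
   over subjects, into `k_spatial` clusters, followed by a Voronoi
   reassignment so each cell belongs to its nearest centroid. Centroids are
   mirrored about the midline plane and right-hemisphere cells are assigned
   to the nearest mirrored centroid, giving `2 * k_spatial` hemispherically
   symmetric clusters with an explicit homotopic pairing. Cells exactly on
   the midline count as left by convention.
2. **Global signal regression.** Each cell's condition-concatenated trace is
   regressed on an intercept and the mean-over-cells trace; residuals are
   exactly orthogonal to the global signal. If the global signal's variance
   is numerically negligible (as after a previous pass) the traces are
   returned unchanged — regressing on a noise direction would otherwise
   remove an arbitrary component.
3. **Functional clustering.** Spatial-cluster traces are correlated within
   each hemisphere and subject; the matrices are averaged over subjects and
   hemispheres (a cluster's row is averaged with its homotopic partner's
   row) into one `k_spatial x k_spatial` matrix, whose rows are clustered by
   k-means with correlation distance into `k_functional` functional
   clusters. Correlation distance is implemented by z-scoring rows and
   running Euclidean k-means, which is equivalent up to a constant factor
   and inherits the invariance to positive affine row transforms. Raw
   correlations (not Fisher-z) are used at this stage; the Fisher transform
   enters only at network construction.
4. **Spatial constraints.** Within each functional cluster, member spatial
   clusters are grouped by single-linkage agglomeration cut at `min_gap`
   (connected groups mutually separated by more than `min_gap`); any group
   whose centroid *diameter* — the maximum pairwise Euclidean distance
   between member centroids — reaches `max_diameter` is split by recursive
   bisecting 2-means; a final repair pass greedily re-merges group pairs
   closer than `min_gap` whenever the merged diameter stays under
   `max_diameter`. The resulting left-hemisphere groups, mirrored into both
   hemispheres, are the parcels; left parcel $p$ and right parcel $p + P$
   are homotopic partners, making the pairing a fixed-point-free involution
   by construction.

The defaults (`k_spatial = 2500`, `k_functional = 100`, `n_replicates =
10`, `max_diameter = 200` px, `min_gap = 60` px) match full-scale studies;
the pipeline and tests scale `k_spatial`/`k_functional` down with the
synthetic population size while keeping the pixel-scale constraints.

A geometric caveat: the diameter cap and the mutual-gap requirement cannot
both hold for every conceivable input (a dense connected blob wider than
`max_diameter` cannot be cut into pieces that are both narrow and mutually
distant). On data whose functional clusters are spatially coherent — the
regime the procedure is designed for, and the regime of the synthetic
generator — the repair pass leaves both constraints satisfied exactly, and
the package asserts them on its outputs.

# Community detection

## Single-layer modularity

Partitions are scored with signed modularity under a **uniform null**
($P_{ij} = 1$), appropriate for correlation matrices and robust to the
resolution limit:

$$Q(\gamma, \{g_i\}) = \sum_{i \ne j} (A_{ij} - \gamma)\,
\delta(g_i, g_j),$$

summed over ordered pairs with the diagonal excluded, so the all-singletons
partition scores exactly zero. $\gamma$ plays the role of an expected
correlation magnitude.

Optimization is a Louvain heuristic written for dense signed matrices:
randomized-order single-node moves (including isolation moves into an empty
module when every existing module is detrimental), module aggregation,
repetition to convergence, plus a flat refinement loop that re-attempts
single-node moves on the unaggregated matrix and re-runs the multilevel
phase until stable. `louvain_optimize()` runs several restarts — the first
from singletons, later ones from random initial partitions — and keeps the
best $Q$. On exhaustively enumerable instances (8-node networks, all 4,140
set partitions) this reaches the global optimum essentially always; the
acceptance suite holds it to at least 95% of the optimum on every instance.

The interesting resolution range is bounded by `gamma_bounds()`:
$\gamma_{\max}$ is the maximum off-diagonal weight (above it singletons are
optimal); $\gamma_{\min}$, the smallest resolution producing two or more
modules, is located by bisection with repeated Louvain runs. Resolutions
are then sampled with replacement from the connection weights inside the
range, so the sweep mirrors the network's weight distribution. The package
default is 1,000 samples (10,000 at full scale); the pipeline's desk
default is 200.

## Hierarchical consensus

The sampled partitions are summarized by a coassignment matrix (fraction of
partitions placing a node pair together) and recursively split: at each
node subset, Louvain clusters the coassignment submatrix minus its
permutation-null expectation (the subset-restricted mean coassignment under
independent relabeling of each partition); a candidate split is accepted
only if its consensus modularity exceeds the `n_perm` permuted-ensemble
null at level `alpha = 0.05`. Accepted splits recurse; the rounds of
splitting become hierarchy levels, each level a refinement of its parent by
construction. The exact permutation statistic is a design choice of this
package — the criterion is a null of "no preferential coassignment beyond
module sizes" — and is documented here rather than hidden in code.

Significance of the hierarchy against surrogates compares, per level, the
empirical maximized $Q$ at the level's representative resolution (the
median of the sampled $\gamma$ whose partitions have the closest module
count) with maximized $Q$ over phase-randomized surrogate networks at the
same resolution; $p = (1 + \#\{Q_{\mathrm{surr}} \ge Q_{\mathrm{emp}}\}) /
(1 + n_{\mathrm{surr}})$, Bonferroni-corrected across levels.

## Multilayer modularity and flexibility

Per-condition networks form layers of a multilayer network; each node is
coupled to itself in all other layers (categorical all-to-all coupling)
with weight $\omega$:

$$Q(\gamma, \omega, \{g_{is}\}) = \sum_s \sum_{i \ne j}
(A_{s,ij} - \gamma)\, \delta(g_{is}, g_{js}) + \omega \sum_i \sum_{s \ne r}
\delta(g_{is}, g_{ir}).$$

Louvain runs on the supra-modularity matrix ($N \cdot T$ nodes), so module
labels are shared across layers. $\omega$ is sampled log-uniformly,
$10^{U[-3, 1]}$ (0.001 to 10), paired with $\gamma$ draws, one optimization
per pair. Node flexibility is

$$f_i = 1 - \frac{2}{T(T - 1)} \sum_{r < s} \delta(g_{i,r}, g_{i,s}),$$

the fraction of layer pairs on which the node's module differs. Mean
flexibility is averaged over runs whose mean modules-per-layer falls in
$[2, 25]$ (discarding near-trivial solutions), weighting qualifying runs
equally; a rank-transformed variant removes baseline differences across
coupling strengths.

# Hubs, similarity, geometry

* **Participation coefficient** (positive weights):
  $p_i^+ = 1 - \sum_c (\kappa_{ic}^+ / k_i^+)^2$; nodes with zero positive
  strength receive 0 by convention. Computed per hierarchy level, averaged,
  and rank-transformed.
* **Absolute strength**: $s_i = \sum_j |A_{ij}|$.
* **z-Rand index** for partition similarity: the count of co-coassigned
  pairs standardized by its exact permutation mean and the
  Traud–Kelsic–Mucha–Porter closed-form variance, computed with exact pair
  counts (safe to $N \le 10^4$); degenerate partitions (all-singletons,
  single-module) are rejected since the variance vanishes.
* **Geometry**: node pairs are binned by centroid distance; per-bin mean
  weight (within- and between-hemisphere separately when labels are given)
  and proportions of four connection classes — anticorrelation, neutral,
  weak positive, strong positive — using thresholds `t_neutral = 0.1`,
  `t_strong = 0.5` in Fisher-z units (the class cut points are a package
  choice, exposed in the configuration). Empty bins report `NA`, never 0.
  `decay_slope()` fits `log(mean |weight|)` against bin centers over bins
  above a noise floor (default 0.05, below which finite-sample correlation
  bias dominates).
* **Hemisphere symmetry**: Pearson correlation between left
  within-hemisphere edge weights and the homotopically reordered right
  ones, on Fisher-z weights for consistency with $A$.
* **Mantel test**: Pearson correlation of upper triangles with simultaneous
  row/column permutations of the second matrix; one-sided
  $p = (1 + \#\{r_\pi \ge r\}) / (1 + n_\pi)$.
* **Similarity reports**: pairwise upper-triangle correlations across
  conditions and subjects, with the fingerprinting contrast — mean
  self-similarity (same subject, different conditions) versus mean
  intersubject similarity.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
zebrafish biology. Cells are sampled uniformly inside one hemisphere of an
ellipsoid (default semi-axes 500, 200, 150 px — proportioned like a larval
brain at the pixel scale implied by the 200/60 px parcel constraints) and
mirrored, so hemispheric symmetry is exact at machine precision. A
two-level module layout (default 2 coarse modules each containing 2 fine
modules) is planted by k-means on midline-folded coordinates, making
modules spatially compact and hemispherically symmetric.

Traces follow a nested Gaussian latent model,

$$x_i(t) = a_f\, v_{f(i)}(t) + a_c\, u_{c(i)}(t) + a_b\, s_i(t) +
g_a\, g(t) + \sigma\, \varepsilon_i(t),$$

with $a_f = \sqrt{\rho_f - \rho_c}$, $a_c = \sqrt{\rho_c - \rho_b}$,
$a_b = \sqrt{\rho_b}$, and $s$ a Gaussian field with correlation
$\exp(-\lambda d_{ij})$ (sampled through a Cholesky factor of the exact
kernel). With `global_amp = 0` and $\sigma = \sqrt{1 - \rho_f}$ the
planted correlations are attained exactly in expectation: $\rho_f$ within
fine modules, $\rho_c$ within coarse, and $\rho_b e^{-\lambda d}$ between
coarse modules — the last giving a log-linear distance decay whose slope is
recoverable by regression. With $\lambda = 0$ and no modules, the
off-diagonal correlation reduces to the closed form
$g_a^2 / (g_a^2 + \sigma^2)$, used as a calibration check. Defaults:
$\rho_f = 0.6$, $\rho_c = 0.3$, $\rho_b = 0.1$, $\lambda = 0.004$/px (an
e-fold per 250 px), `global_amp = 0.2`.

Two structured extensions support the condition and subject analyses:

* **Flexible cells.** A designated subset (by default one fine module)
  is reassigned to a condition-specific target module under each
  non-spontaneous condition. Under spontaneous conditions the same cells
  split their fine-module variance between their own module and their remap
  targets (`connector_mix = 0.5`), so planted flexible nodes are also
  planted connector hubs — the configuration under which a positive
  flexibility–participation correlation is a planted, testable property.
* **Subject fingerprints.** Each subject receives a random fine-module
  coupling matrix (scale `subject_loading_sd`) through which every cell
  loads on all module latents, drawn once per subject and reused across
  conditions. The coupling is constant within modules deliberately: a
  per-cell i.i.d. perturbation would be averaged away by parcellation,
  leaving no subject identity at the node level. The default scale 0.5
  makes the fingerprint comparable to condition-level differences, so
  subjects are more similar to themselves across conditions than to other
  subjects, and intersubject similarity sits clearly between 0 and 1 —
  qualitatively matching the substantial between-animal variability of
  real recordings.

What the generator does **not** emulate: calcium indicator kinetics, spike
trains, motion artifacts, heavy-tailed fluorescence marginals, or real
neuroanatomy. All analyses here use zero-lag correlations, so second-order
structure suffices; passing tests demonstrate correctness of the analysis
chain on data with known second-order ground truth, not performance on raw
fluorescence with indicator dynamics.

# Numerical and design choices

* Modularity sums run over ordered pairs with the diagonal excluded,
  consistently in the optimizer, the scorer, and the brute-force test
  oracles (the unordered convention differs by an irrelevant factor 2).
* Louvain moves accept gains above $10^{-12}$; empty-cluster k-means
  restarts and all stochastic steps derive their seeds deterministically
  from a caller-supplied master seed, and library code restores the
  caller's RNG state.
* The multilayer quality function is implemented from its verbal
  definition (intra-layer modularity blocks plus categorical interlayer
  coupling); coupling is all-to-all across layers, not an ordinal chain.
* Pair counts in the z-Rand components are computed in double precision
  from exact integer-valued counts; the closed-form variance is validated
  against a permutation Monte-Carlo oracle in the test suite.
* Serialization uses CSV with 17 significant digits (exact float64 round
  trip) plus JSON sidecars; partitions are written with 0-based node ids
  and 1-based module ids.
* Desk-scale problem sizes used by the pipeline defaults and the test
  suite: 600–2,000 cells, 2–3 subjects, 150–2,000 frames, 30–80 spatial
  clusters, 60–500 resolution samples, 100–200 surrogates. These are the
  package's chosen study conditions for synthetic experiments; full-scale
  parameters (2,500 clusters, 10,000 samples, 1,000 surrogates) remain the
  documented defaults of the corresponding parameter objects.

One desk-scale caveat: connector planting acts at the cell level, and
parcel aggregation plus the shared global signal raise every parcel's
baseline participation, so the parcel-level flexibility–participation
correlation in the pipeline report, while positive for most seeds, can come
out near zero for some. The cell-level planted experiment (flexible
connector nodes analysed without aggregation) expresses the positive
relationship reliably and is what the test suite asserts.

# Known limitations

* Connectivity is zero-lag linear correlation: undirected, non-causal, and
  blind to lagged or nonlinear coupling.
* Parcels are fixed across subjects and conditions; subject- or
  condition-specific parcel boundaries are out of scope.
* The consensus split criterion is one realization of "split only when
  coassignment exceeds a permutation null"; other statistics would yield
  slightly different hierarchies.
* Louvain is a heuristic; optimality is verified exhaustively only at
  small $N$, and large-$N$ results are ensembles over restarts and
  resolutions, not certified optima.
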