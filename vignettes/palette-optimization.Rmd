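---
title: "Spatially aware palette assignment: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware palette assignment: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatpal)
```

## What the method models

A clustered 2-D point cloud — cells in a UMAP/t-SNE embedding, or spots on
a tissue slide — is to be colored with a user-supplied categorical
palette. The quantity being optimized is not the palette itself but its
*assignment*: which cluster receives which color. The premise is that
color confusability only matters between clusters that are spatially
adjacent, so the method (i) estimates a spatial footprint per cluster,
(ii) scores adjacency of every cluster pair, and (iii) finds an injective
color assignment that maximizes adjacency-weighted color separation.

### Footprints and hot grid points

Each cluster's footprint is a kernel density estimate evaluated on a
single grid shared by all clusters. The KDE is the classical product
Gaussian kernel: at grid node $(g_x, g_y)$,

$$\hat f(g_x, g_y) \;=\; \frac{1}{n}\sum_{i=1}^{n}
  \frac{1}{\sigma_x\sigma_y}\,
  \phi\!\Big(\frac{g_x-x_i}{\sigma_x}\Big)\,
  \phi\!\Big(\frac{g_y-y_i}{\sigma_y}\Big),
  \qquad \sigma_\bullet = h_\bullet/4,$$

with per-axis bandwidths $h$ from the normal-reference rule
$h = 4 \cdot 1.06\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\, n^{-1/5}$,
computed per cluster from that cluster's points. The $h/4$ kernel standard
deviation follows the convention of the classical 2-D KDE implementations
this estimator is interchangeable with, which matters only in that the
bandwidth numbers users see are on the familiar scale.

A grid point is *hot* for a cluster when the cluster's density there
strictly exceeds a cutoff. The cutoff is calibrated by a permutation null:
the cluster labels are permuted once (coordinates fixed, cluster sizes
preserved), densities are refitted for the permuted memberships with
bandwidths recomputed from those memberships, and each cluster's cutoff is
the 95th percentile of its permuted field over all grid values. Under the
permutation a "cluster" is a spatially random subsample, so its density
field is what no-structure looks like at that cluster's size; exceeding
its upper tail marks genuine spatial concentration. Spatial adjacency of
clusters $a$ and $b$ is then the Jaccard index of their hot sets,
$J_{a,b} = |S_a \cap S_b|/|S_a \cup S_b|$.

### The objective and the search

Given the palette's pairwise color distance matrix $D$ (below), the score
of an injective assignment $P$ is

$$\mathrm{score}(P) \;=\; \sum_{a < b} J_{a,b}\; D_{P_a, P_b}.$$

Summing over unordered pairs halves the equivalent double sum over all
ordered pairs; the factor 2 cannot change the argmax, so the cheaper form
is used. The search is best-of-$N$ random restarts (uniform injective
assignments) followed by greedy pairwise exchange: each proposal swaps the
colors of two uniformly chosen clusters — or, when the palette has more
colors than clusters, swaps one cluster's color with an unused color, each
candidate swap equally likely — and is accepted only on a strict score
increase. Ties are rejections and count toward the early-stopping
patience, which resets on every acceptance. The returned score can
therefore never fall below the best restart, and the running-best trace is
non-decreasing by construction.

### Color distances and CVD simulation

Colors are parsed from `#RRGGBB` into channels on $[0,1]$ (exactly
byte/255). The distance is weighted Euclidean in RGB,
$D_{e,f} = \sqrt{\sum_c w_c (e_c - f_c)^2}$; scaling all weights by $k$
scales every distance by $\sqrt k$ and leaves the argmax unchanged, so
only relative weights matter. Perceptually uniform spaces (CIELAB,
CIEDE2000) are deliberately out of scope: the method's contract is RGB
Euclidean distance with optional channel weights, and the channel weights
are the supported lever for perceptual emphasis.

For color-vision-deficiency-aware output, colors are transformed before
distances are computed, using the severity-parameterized 3×3 matrices of
Machado, Oliveira & Fernandes (2009). The matrices are defined on
linear-light RGB, so channels are sRGB-decoded, multiplied, clipped to the
unit cube and re-encoded; severities between the published 0.1 steps are
linearly interpolated, and severity 0 is exactly the identity. The
matrices have unit row sums, so neutral grays are fixed points — a useful
sanity property the tests assert. Published alternatives (dichromat-style
lookup, gamma-space application) differ numerically but not structurally;
since the transform only enters through the distance matrix, modest
numerical differences move scores, not usually argmaxes.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `grid_size` | 100 | grid points/axis | standard lattice for 2-D KDE maps; 10⁴ nodes resolve tens of clusters while keeping exact Jaccard sets cheap |
| `percentile` | 95 | % of permuted field | upper tail of the spatially-random null; lower values grow footprints and mark more pairs adjacent |
| `n_restarts` | 1000 | assignments | samples the permutation space densely for realistic cluster counts |
| `max_exchanges` | 2000 | proposals | refinement budget after the best restart |
| `patience` | 500 | consecutive rejections | stops refinement once improvements have plausibly dried up |
| `weights` | (1,1,1) | unitless | plain RGB distance unless the user wants channel emphasis |
| `cvd`, `cvd_severity` | none, 1 | — | simulation off by default; severity 1 is full dichromacy |
| `seed` | 1 | — | one stream drives permutation → restarts → exchanges, in that order |

## Numerical and degenerate-input choices

* **One global grid.** Jaccard over grid-point sets is only meaningful on
  a common lattice, so every cluster (and every permuted pseudo-cluster)
  is evaluated on the grid spanning the pooled bounding box. A
  per-cluster extent would make hot sets incomparable.
* **Zero-range axes** are padded by ±0.5 coordinate units, with a warning,
  so degenerate inputs (all points on a line) still yield a grid.
* **Tiny clusters.** The bandwidth rule needs two points and positive
  spread; failing that, the bandwidth falls to a floor of 10⁻⁶ of the
  grid's axis range, so a 1-point cluster contributes a single narrow
  kernel rather than a crash. Zero IQR with positive sd falls back to the
  sd term alone. The formula applies from *n* = 2 upward — its value at
  two points is well defined and tested against hand evaluation.
* **Percentiles** use linear interpolation between order statistics (the
  ecosystem's default quantile convention), over all grid values.
* **Strict inequality** defines hotness (density > cutoff); an empty hot
  set is legal and warned about, and a Jaccard 0/0 (two empty sets) is
  defined as 0 — no footprint is no evidence of adjacency.
* **Canonical cluster order** is lexicographic on the label text with a
  locale-fixed sort, used for all matrix indexing and file output, which
  is what makes repeated runs byte-identical.
* **Exact score comparisons.** All search stages score assignments with
  the same arithmetic (same summation order), so "the refined score is at
  least the best restart" holds exactly, not merely to rounding error.
* **Duplicate palette colors** are permitted with a warning; their mutual
  distance is 0 and the optimizer simply avoids placing them on
  overlapping pairs when it can.

## Design choices where the design was open

* **Permutation count.** The cutoff uses one label permutation, exposed to
  the caller through the run seed. Cutoffs (hence hot sets and J) vary
  across seeds; fixing the seed fixes the whole pipeline. Averaging many
  permutations would stabilize cutoffs at proportional cost and is left
  out to keep the contract simple.
* **Label permutation preserves cluster sizes** (the label vector is
  shuffled), rather than resampling sizes; the null should change only
  *where* a cluster of that size sits.
* **Palettes larger than the cluster count** are supported: unused colors
  wait in a pool, and proposals include cluster↔pool swaps with
  probability proportional to the pool's share of candidate swaps, so an
  initially unassigned color can still enter the solution.
* **Restarts strictly precede refinement** (best-of-restarts, then one
  exchange pass), keeping the two phases separately testable.
* **Exhaustive enumeration** over all injective assignments is shipped as
  `exhaustive_search()`, usable as ground truth up to roughly 10⁶
  assignments. On random small instances (3–6 clusters) the default
  stochastic search recovers the enumerated optimum in ≥95% of runs and
  by construction can never exceed it.

## What the synthetic generator does and does not emulate

`make_blobs()` draws isotropic Gaussian clusters and `overlap_ladder()`
produces two equal blobs whose separation shrinks from 10 spreads to 0,
reusing the same sampled offsets at every level so the levels differ only
in separation. This captures the one property the method consumes —
controlled spatial overlap between compact clusters — and nothing else.
Real embeddings have anisotropic, curved, variable-density clusters;
UMAP distorts global distances; spatial data have tissue boundaries and
holes. None of that changes the pipeline's contracts (the KDE, cutoff,
Jaccard and optimizer see only coordinates), but passing tests on blobs
demonstrates correctness of the machinery, not visual optimality on any
particular real dataset. Test and acceptance runs use blob clusters of
120–500 points and instances of up to 10 clusters, sizes chosen so the
exhaustive oracle stays exact and properties are sampled across dozens of
seeds.

## Known limitations

* The color model is RGB-Euclidean, not perceptually uniform; channel
  weights and CVD simulation are the only perceptual levers.
* Adjacency is resolved at grid resolution: clusters thinner than a grid
  cell can miss overlaps, and very diffuse clusters may have empty hot
  sets at the 95th-percentile cutoff.
* The optimizer is a stochastic local search: for large cluster counts the
  result is a high-scoring assignment, not a certified optimum (certified
  optima are available via `exhaustive_search()` only at small sizes).
* One permutation defines the null; seeds with atypical permutations give
  atypical cutoffs. Reported overlap matrices should be read per-seed.
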