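---
title: "Methods: surface-based connectome construction, box covering and within-area modularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based connectome construction, box covering and within-area modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `triconnectome`, in the spirit of a methods section: what is
computed, under which assumptions, and where a design decision was
genuinely open, why it was settled the way it was.

## The network model

Nodes are the triangles of a downsampled cortical (or cortical-like)
surface mesh. Two connectivity sources are combined:

* **Local lateral connectivity**: each triangle is linked to the (up to
  three) triangles sharing an edge with it. On a closed manifold this
  lattice is 3-regular and connected, which guarantees the combined
  network is connected — a prerequisite for box covering. It stands in
  for short-range grey-matter connectivity that diffusion imaging cannot
  resolve; because every node receives the same number of local links,
  it adds no degree heterogeneity of its own.
* **Long-range connectivity**: each streamline contributes a link
  between the triangles whose centroids are nearest (Euclidean) to its
  two endpoints. Endpoint snapping is exhaustive nearest-neighbor with
  ties broken to the lowest triangle id; streamlines whose endpoints
  snap to the same triangle are counted separately and contribute no
  edge (a binary self-loop would be meaningless in the graph analyses).

The two edge sets are summed and binarised. Multiplicities are recorded
before binarisation (they matter for diagnostics, not for the analyses).
Meshes and streamlines are assumed to share one coordinate frame in mm;
the package performs no registration.

Streamlines are filtered first: kept iff length ∈ [`min_length`,
`max_length`] = [10, 300] mm and maximum turning angle ≤ 60°, and (when
a grey-matter mask is supplied per endpoint) both endpoints in-mask.
The turning angle is evaluated **per interior vertex** between
consecutive segment directions, the common convention in tractography;
the 60° criterion could also be read cumulatively, so the reducer (max
over interior vertices) is a deliberate, documented choice. Rejections
are attributed to the first failing rule in the fixed order
length-short, length-long, angle, mask, so accounting is deterministic
and sums exactly to the input count.

## Box covering and the fractal dimension

`membCover()` implements maximum excluded mass burning (MEMB) under the
radius criterion: for box size ℓ_B, the covering radius is
r_B = ⌊(ℓ_B − 1)/2⌋; centers are chosen greedily by maximum excluded
mass (uncovered nodes within chemical distance r_B) and every node is
assigned to a center at minimal chemical distance, ties resolved by
burning order through a level-synchronous multi-source BFS so each box
induces a connected subgraph. Pairwise distances inside a box are
therefore ≤ 2 r_B ≤ ℓ_B − 1, i.e. strictly below ℓ_B.

Numerical/algorithmic choices:

* **Even box sizes.** Under the radius criterion N_B depends on ℓ_B only
  through r_B, so N_B(2r+1) = N_B(2r+2): the curve has plateaus at even
  ℓ_B. The default fit range for `fitFractalDimension()` is therefore
  the odd sizes {3, 5, 7, 9} — including the even duplicates would
  double-weight each radius and bias the slope. The full curve over
  2..10 is still computed and reported.
* **ℓ_B = 2.** The radius criterion degenerates to singletons, so a
  greedy pairing on the diameter-1 criterion is used: nodes in
  increasing degree order pair with their lowest-degree uncovered
  neighbor. Leaf-first pairing is optimal on trees (hence paths and
  stars) and on cycles and cliques.
* **Restarts.** N_B is defined as a *minimum*. A single deterministic
  greedy pass with lowest-id tie-breaking raster-scans highly symmetric
  graphs (on a 30×30 periodic lattice it packs radius-3 boxes ~60%
  above the ideal diamond tiling), flattening the fitted slope. The
  cover is therefore taken as the best of 4 greedy passes — one
  lowest-id pass plus three passes with seeded uniform tie-breaking —
  followed by pruning of centers whose entire ball is covered by other
  centers. The result is still deterministic given (parameters, seed),
  and on all small-graph fixtures it never goes below the exhaustive
  minimum (`bruteForceMinCover()`, a bitmask dynamic program over
  connected radius-feasible boxes, used as the oracle up to 12 nodes).
* **Fit.** d_B is the negative OLS slope of log(N_B/N) on log ℓ_B;
  standard error and R² are reported. R² near 1 over the fitted range is
  the operational indicator of scale-invariance; d_B from a poor fit is
  not meaningful.

## Resolution scan, null comparison and consensus

`louvainPartition()` optimises Q(γ) = (1/2m) Σ_ij [A_ij − γ k_i k_j /
(2m)] δ(c_i, c_j). The optimizer is igraph's Louvain implementation with
its resolution parameter; the run seed controls the randomized
optimization order, so repeated runs explore different local optima. The
*reported* Q is always recomputed from the final membership by direct
summation (`computeModularity()`), keeping the quality function
independent of the optimizer.

`gammaScan()` runs, per γ on the default grid 0.6–1.4 step 0.02 (41
values), 25 partitions of the data network and 25 of **one** G(n, m)
random realization with the same node and edge counts;
Q_MAX(γ) = Q̄_net − Q̄_rand, and γ* is the grid maximiser (ties to the
smaller γ, i.e. coarser modules, for determinism). Whether the null
should be one realization per scan or one per run is ambiguous in
common practice; one-per-scan is the default and the symmetric 25-run
treatment mirrors the data side. Null connectivity is deliberately not
enforced — modularity is well-defined on disconnected graphs, and box
covering is never applied to nulls.

The consensus at γ* follows the co-classification approach: the n×n
matrix of pairwise same-module frequencies over the 25 runs is
thresholded at τ = 0.5, re-clustered as a weighted graph at γ = 1, and
iterated (up to 20 times) until all re-clustering runs agree. Module
labels from different runs are never compared directly — "most common
membership" is only meaningful through co-classification, since labels
are arbitrary per run. A label-alignment (assignment-problem) variant
was considered and not included; the co-classification method is the
standard citable procedure and is label-permutation invariant by
construction.

`withinAreaModules()` applies the scan independently to each area's
induced subgraph (areas with fewer than 3 nodes are skipped with a
warning; disconnected induced subgraphs are reduced to their largest
component with the remainder reported unassigned). Module ids are
namespaced `area.k`. All of this derives from one master seed through a
documented integer mixing function (`deriveSeed()`), so a single seed
pins down all 41 × 25 × 2 runs per area.

## Module-pair targeting statistics

For areas A ≠ B, `modulePairDensities()` computes, per module pair
(i ⊂ A, j ⊂ B), density = inter-area edges between i and j divided by
|i|·|j|. Only edges with one endpoint in each area count. The exact
identity Σ_ij density(i,j)·|i|·|j| = inter-area edge count is asserted
in the tests. `compareToRandom()` contrasts the pooled zero-density
fraction and the median nonzero density against 5 same-size random
networks, with modules **re-detected on each null** by the same scan —
transplanting the data partition onto the null would conflate partition
structure with edge placement.

Spatial statistics make two deliberately simple, bounded choices of
effect size, recorded in the output metadata: rank-biserial correlation
(with a permutation p-value on group labels) for the
connected-versus-unconnected centroid-distance contrast, and Cramér's V
(no bias correction) for the targeted-versus-class contingency table.
Module surface class is the majority class of member triangles, ties
falling to saddle; "targeted" means participating in at least one
nonzero-density between-area pair (threshold configurable). With few
modules the V statistic is noisy upward (its null expectation scales
like √(df/n)), and when every module is targeted — common in small
scenes — the table degenerates and V is reported as 0 with a warning.

## Surface curvature classes

Discrete Gaussian curvature is the vertex angle deficit divided by the
barycentric vertex area (one third of incident triangle areas; the
mixed-Voronoi refinement changes little on near-uniform meshes). Mean
curvature is the cotangent-Laplacian mean-curvature vector projected on
the outward vertex normal. The sign convention — chosen because no
universal standard exists, and recorded here and in the docs — makes a
convex surface (sphere, gyral crown) have H < 0. Classification per
triangle (mean of its vertices): K > 0 with H < 0 gyrus, K > 0 with
H > 0 sulcus, K < 0 saddle; |K| below 1e−8 mm⁻² is treated as flat and
classified by the sign of H alone (exact zero falls to saddle). Meshes
must be consistently outward-wound; inconsistent or inward orientation
is an error instructing the caller to fix the winding, not silently
corrected. The angle-deficit sum is validated against Gauss–Bonnet
(4π for the sphere, 0 for a torus) to 1e−6 relative tolerance.

## The synthetic scene: what it emulates and what it does not

`makeSyntheticScene()` defines the study conditions used throughout the
tests: a subdivision-3 icosphere (1280 triangles) of radius 50 mm with
sinusoidal radial bumps (amplitude 5 mm, frequency 6) yielding all three
curvature classes; 4 contiguous longitude-sector areas; 5 planted
modules per area grown by seeded breadth-first region growing with
random tie-breaking (guaranteeing spatial contiguity); 5000 streamlines
sampled at 0.625 mm steps; endpoint noise 0.5 mm; 5% invalid
contamination (⌊n·fraction⌋ streamlines placed deterministically at the
tail, violating exactly one exclusion rule each, so filter round-trips
are exact). Valid streamlines are circular arcs bulging radially
outward, constructed so length ≥ 10.5 mm and per-step turning stays
far below 60° (arc radius ≥ length/2π ≈ 1.7 mm gives ≤ ~21° per
0.625 mm step); this makes "valid" a geometric guarantee, not a
statistical one.

The pair map assigns each planted module a target module in another
area (uniformly, or nearest-centroid to plant a distance association).
With `withinModulePairs = TRUE` (default) each module also maps to
itself, emulating the short within-module association fibers that
dominate within-area connectivity; this is what gives the within-area
scan planted structure to recover. With `FALSE` all streamlines are
between-area and the within-area subgraphs are identical across
targeting fidelities — the configuration used when contrasting
fidelities, so that detected-module granularity cannot confound the
contrast.

What passing tests show — and what they do not: the generators emulate
endpoint geometry, exclusion-rule contamination and module-targeted
termination, but not tractography physics (curvature-dependent seeding
biases, gyral bias, distance-dependent false negatives), not
heavy-tailed degree structure, and not realistic areal geometry. At
this scale (≈3,750 module pairs, ≈4,750 kept streamlines) the uniform
non-targeted background is dense relative to the number of module
pairs: raising targeting fidelity concentrates most edges into planted
pairs *and* scatters the remaining background into many single-edge,
low-density pairs, so the **median** nonzero density falls with
fidelity even as the zero-density fraction (and its ratio to random
networks) rises monotonically. In a full-scale network the quadrilateral
count exceeds the background edge count by orders of magnitude and the
median moves the other way. The zero-fraction statistics are therefore
the scale-robust readout of targeting here, and the test suite's
median-direction expectations at full-scale behavior are documented as
not attainable at this problem size.

## Problem sizes and reproducibility

The test suite and the acceptance script use sizes chosen to exercise
every code path at interactive cost: subdivision-2 meshes (320
triangles) for unit tests; the standard subdivision-3 scene for
end-to-end properties; the full 41-point γ grid with 25 runs on the
160-node planted-partition benchmark; reduced scans (γ step 0.1, 5
runs) for within-area detection on 1280-node scenes; 2000–10000
permutations for permutation tests. Every stochastic step draws its
seed from a master seed via `deriveSeed()`; rerunning any pipeline or
script with the same seed reproduces all numeric outputs byte-for-byte
(manifest wall times excepted).

On-disk conventions: all indices are 0-based in files (OFF, PLY,
MatrixMarket as per its 1-based format spec, TSV tables with
`triangle_id` 0-based) and 1-based in memory, matching R; coordinates
are float64 except TCK, whose format stores float32 (round trips are
lossy at float32 precision and documented as such); networks are
written as MatrixMarket `pattern symmetric` with a companion node
table.

## Known limitations

* MEMB is a greedy upper bound on the true minimum box count; restarts
  and pruning tighten but do not close the gap, which is largest on
  highly symmetric graphs at large r_B.
* The Louvain optimizer's exploration heuristics are igraph's; the
  consensus step absorbs run-to-run variability, but exact module
  boundaries on weakly modular graphs remain seed-sensitive.
* Curvature classification on coarse meshes (subdivision ≤ 2 at bump
  frequency 6) aliases the bumps and can collapse to a single class.
* The FreeSurfer binary surface format is not read; convert to OFF/PLY
  upstream. No volume (NIfTI) handling: grey-matter masks enter as
  per-endpoint booleans computed by the caller.
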