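---
title: "celltrax: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celltrax: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltrax)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter (with units and
defaults), the numerical choices, what the simulators do and do not emulate,
and the design decisions that were genuinely open.

## Data model and coordinates

All analyses run on a *cell table*: a tibble with one row per object per
timepoint, `cell_id` (≥ 1, unique within a frame), optional `frame`,
centroid coordinates `x`, `y`(, `z`) in micrometres, and optional
`track_id` where **values above 0 mark tracked objects** and 0 is the
untracked sentinel — `filtered_population(cells, "tracked")` reproduces
exactly this rule. Coordinates are continuous, 0-based, with voxel centres
at (index − 0.5) × voxel size, so images with different pixel sizes meet in
one physical coordinate system. Tables order axes `x, y, z`; image arrays
are stored `(z,) y, x` as microscopy stacks are, and converters between the
two are always explicit, never implied.

Label images come from TIFF files (`read_label_image()`, voxel size from
resolution metadata or a caller override) or in-memory arrays. Labels are
preserved exactly on read; float pixel data is refused unless an explicit
cast is requested. Transcript point tables are rasterised by
`points_to_image()`: points are binned and each pixel receives the summed
weight within a Chebyshev radius — a **box kernel** of side 2·radius + 1.
A disc kernel would be equally defensible; the box was chosen because the
local sum is separable, exactly conservative for interior points
(total = Σ weights × (2r+1)²; a tested invariant), and trivially
explainable. The kernel shape is visible in the function contract so it can
be revisited without breaking callers.

## Object measurement and shape descriptors

`measure_objects()` computes per label: voxel-count centroid, volume
(voxel count × voxel volume), per-channel mean intensity, exposed
voxel-face surface extent, and the eigenvalues λ₁ ≥ λ₂ (≥ λ₃) of the
**gyration tensor** — the covariance of voxel positions in µm. Positions
are intensity-unweighted: the descriptors are morphological, not photometric,
and this is the simplest contract that can be verified against closed-form
shapes. From the eigenvalues:

* asphericity b = λ₁ − (λ₂ + λ₃)/2 (3D) or λ₁ − λ₂ (2D), in µm²; 0 for
  anything with isotropic second moments,
* relative shape anisotropy κ² = (d/(d−1)) (Σλ²/(Σλ)² − 1/d) ∈ [0, 1]
  (0 sphere, 1 line),
* prolateness: the normalised cubic invariant √2·Πμᵢ/(Σμᵢ²/3)^{3/2} of the
  centred eigenvalues μᵢ = λᵢ − λ̄, which lands exactly on +1 for a rod and
  −1 for a disc; in 2D it degrades gracefully to the eccentricity-like
  (λ₁ − λ₂)/(λ₁ + λ₂).

These are checked against a 1×1×9 voxel rod (κ² = 1, prolateness = +1), a
single voxel (all zero), rotated rasterised ellipses (rotation invariance up
to discretisation) and the analytic uniform-ellipsoid tensor diag(a², b²,
c²)/5.

Merging independently produced segmentations (`merge_labels()`) resolves
voxel conflicts **first-wins by input order**. The choice is arbitrary but
must be deterministic; the provenance table (output label → source, original
label) retains enough information to layer any other policy on top.
Channel cleanup uses division, `signal / (divisor + offset)`, rather than
subtraction: it needs no per-image scaling factor, which is what makes batch
processing workable; the offset (> 0, default 1) guards the division and
damps the correction in dark regions.

## Track kinematics

`step_features()` converts tracked centroids to per-step records: speed in
µm/min computed over the **true elapsed time** (a step across a dropped
frame uses 2Δt, so gaps never inflate speeds), and the unsigned turning
angle in degrees between successive displacement vectors — unsigned because
3D has no signed convention, and 2D follows for consistency. Angles are
undefined (NA) at track starts and around zero-length steps rather than
silently 0. Steps that bridge a gap are flagged and **dropped from HMM
fitting by default** (their features mix two timescales); they still count
in whole-track statistics, which are about the physical path.

`track_stats()` gives straightness = net displacement / total path length,
which lies in [0, 1] by the triangle inequality — it is never clamped; a
zero-length (stationary) track gets straightness 0 and a `stationary` flag.
The acquisition interval is a parameter (`dt_seconds`, default 10 s in the
simulators, a typical two-photon frame interval); speeds are always reported
in µm/min regardless of it.

`link_tracks()` is deliberately simple plumbing: greedy globally-shortest
one-to-one frame linking with bounded gap bridging. It is adequate for
well-separated objects (the tested regime) and is not a substitute for a
probabilistic tracker; data that arrives already tracked bypasses it.

## Behaviour states: Gaussian HMM

Step features (default speed and turning angle; optionally log(1+speed)
since speeds are right-skewed) are z-scored over the pooled dataset and
modelled by a K-state hidden Markov model with **diagonal-covariance
Gaussian emissions**. One model is fitted per dataset — pooling all tracks —
because behaviours are compared across movies, which requires a shared state
space; decoding is per track. Defaults: movement HMM K = 3 (configurable),
shape HMM K = 4 over (asphericity, prolateness, κ², volume).

Fitting is Baum–Welch EM with scaled forward–backward recursions (compiled;
per-observation normalisation, so long tracks cannot underflow), tolerance
1e-4 on the absolute log-likelihood improvement, at most 500 iterations,
best of `n_restarts` seeded initialisations. Three numerical guards matter:

* the log-likelihood is asserted non-decreasing at every iteration — a
  decrease is a bug, not a warning;
* emission variances are floored at 1e-4 (z-scored scale) so a state cannot
  collapse onto a point;
* after fitting, states are relabelled by ascending first-feature mean, so
  identical data and seed give bit-identical models.

Viterbi decoding breaks ties toward the lower state index (determinism).
Per track, the decoded path yields a state **occupancy** vector (sums to 1)
and **observed transition frequencies** — counts of consecutive decoded
state pairs normalised by the number of pairs. Transition *frequencies*
from the decoded paths are used rather than the fitted transition matrix
because the fitted matrix is global while clustering needs per-track
variation. K = 1 is allowed (with a warning) and reduces to sample moments;
sequences shorter than 2 after gap/NA splitting are excluded.

## Behaviour clusters

`assemble_behaviour_matrix()` joins track statistics, occupancies,
transition frequencies and optional per-track extras — e.g. the mean, sd,
95% upper (qUp) and 5% lower (qLow) quantiles of per-step distance to a
structure (`structure_distance_summary()`) — and z-scores every column.
Degenerate columns (sd below machine noise, e.g. a single track) use an sd
floor of 1, yielding zeros rather than NaNs; residual missing values are
imputed to the column mean (0 after scaling) with a message.

Clustering is Leiden community detection (modularity objective) on an
undirected union-of-neighbourhoods Euclidean kNN graph, k = 20. The
**resolution default is 0.25**, a deliberate design choice: behaviour
phenotypes at the whole-track level number a handful, whereas modularity
granularity at resolution 1 scales with graph size — on cohorts of a few
hundred tracks it reliably splits feature-homogeneous groups into clusters
whose centroids are indistinguishable. At 0.25 the four-mode simulation
benchmark is recovered with ARI ≥ 0.9 across seeds while genuinely distinct
phenotypes stay separate; users digging for finer substructure should raise
the resolution (it is a first-class argument), and the seed is threaded
through every stochastic call.

## Spatial statistics

*Neighbour graphs.* Delaunay adjacency is computed by checking candidate
simplices against the empty-circumcircle/-circumsphere property directly
(compiled brute force, O(n³)–O(n⁴)). This is slower than a flip or
incremental algorithm but transparently correct and robust, and image fields
of view hold hundreds, not millions, of cells; the documented practical
limits (~500 points in 2D, ~150 in 3D per call) reflect that. Exact
co-circular ties (e.g. grid-aligned cells) are resolved by a deterministic
index-keyed jitter of relative magnitude 1e-9 applied before triangulation —
the same table always gives the same graph — while reported edge distances
use the original coordinates. Collinear/coplanar inputs raise a degeneracy
error that suggests jittering. The nearest-neighbour-subgraph property
(every point's nearest neighbour is Delaunay-adjacent) is tested on random
instances.

*Interactions.* The interaction partner of a cell is its **closest adjacent
cell** in the neighbour graph, optionally restricted to partner populations;
cells with no admissible partner report NA and are counted, not dropped.
Region-to-region interactions map each cell to its single nearest other cell
(any region, so the matrix diagonal measures self-cohesion) and
row-normalise the tally.

*Aggregates.* DBSCAN follows the textbook definition: a core point has at
least `min_pts` points (self included — the standard convention) within
`eps`. The headline parameterisation is eps = 20 µm, min_pts = 4. Note the
20 µm figure is quoted as an aggregate *diameter* in the motivating
analyses, but DBSCAN has no diameter parameter; it is adopted directly as
eps (the neighbourhood radius), which is flagged here and in the function
documentation. Labelling is deterministic: clusters are numbered by lowest
member `cell_id`, and a border point reachable from several clusters joins
the one containing the lowest core id among its in-range cores (DBSCAN's
classic order-dependence removed).

*Niches/regions.* Neighbourhood composition profiles include the centre
cell (a neighbourhood is never empty; compositions always sum to 1, tested
to 1e-12). Defaults follow the two standard use cases: 50 µm radius for
antibody-panel images, 100 µm for transcript panels; regions default R = 3
and both are always explicit arguments. K-means is Lloyd's algorithm, best
of `n_init = 10` seeded starts by within-cluster SSE, with SSE monotonicity
asserted and empty clusters re-seeded at the farthest point; the final
assignment is exactly nearest-centroid. The reference `stats::kmeans`
implementation serves as an independent cross-check in the tests, not as
the implementation, because the contract (seeded starts, re-seeding policy,
monotonicity assertion) is part of the module's surface.

*Structure distances and contacts.* Distance to a structure is the exact
1-nearest-neighbour Euclidean distance to its point cloud. Contacts
threshold the minimum separation at `max_dist` (default 5 µm): with surface
point samples, minimum sample-to-sample distance; without, centre distance
minus both **volume-equivalent sphere radii**, floored at 0. The sphere
fallback preserves the thresholded-minimum-distance contract for roughly
convex cells but will underestimate contact for strongly elongated or
concave shapes — supply surface samples in those settings.

## Gating

Gates are named 2D shapes over any two table columns, nested in a tree;
membership is parent-intersected top-down and the child ⊆ parent invariant
is asserted after every evaluation. Point-in-polygon is **even-odd and
boundary-inclusive**: a point on an edge or vertex is inside. Inclusivity is
a convention choice (conventions differ across tools); it was picked so a
gate drawn through data points behaves predictably, and it is pinned by
tests against an independently written even-odd oracle. Axis transforms are
linear or log10(v + 1) — the +1 admits zero intensities, ubiquitous in
imaging-derived tables. Gates serialise to portable JSON.

## Flow fields and anisotropy

Each step's velocity vector is binned at the step's start position
(default bin 50 µm) and averaged per bin; bins with fewer than `min_count`
(default 3) steps are masked. Anisotropy is the **nematic order parameter**
of the unmasked bins' unit directions: the leading eigenvalue of
Q = ⟨û ûᵀ⟩ − I/d, rescaled by d/(d−1) to [0, 1]. It is 1 for a parallel (or
anti-parallel — nematic symmetry is deliberate, bidirectional streams are
collective) field and concentrates near 0 at rate ~1/√n for isotropic
directions; both limits and the reversal/rotation invariances are tested.
This scalar is this package's operational definition of flow anisotropy —
documented as such rather than imported from any external flow-estimation
tool, whose exact formula it does not claim to reproduce; only the
qualitative contrast (persistent collective flow scores above isotropic
motion) is claimed, and it is tested over 20 seeded repetitions.

## Simulators: what they emulate, and what they do not

`simulate_tracks()` is a persistent random walk: heading = normalised blend
of previous heading (weight = persistence) and a fresh random unit vector;
step length = clipped-Gaussian speed × Δt. The four canonical modes span
the behaviour phenotypes seen in lymph-node imaging — directed (12 µm/min,
persistence 0.95, prolate/aspherical shape program), meandering (7 µm/min,
0.6), scanning (3 µm/min, 0.15, low asphericity), aggregating (2.5 µm/min
plus drift of a fixed fraction, 0.08, of the remaining distance to a shared
attractor per step, capped at the drawn cell speed so distant cells
chemotax at cell speed rather than teleporting). Speeds sit in the range
reported for T cells and DCs; Δt defaults to 10 s. Shape programs emit
Gaussian shape descriptors per step so shape-state models can be
benchmarked.

`simulate_tissue()` places populations as Gaussian blobs (one per
population, centres on a circle, sd = field/12) or 90%-dominant vertical
stripes, records the true region per cell, and can emit a sinusoidal
"vessel" point tube for structure-distance analyses.
`simulate_hmm_sequences()` is exact ancestral sampling from a model.
`simulate_ellipsoid_label()` voxelises solid ellipsoids for measurement
benchmarks. All randomness flows through R's seeded generator: identical
seeds give bit-identical outputs (tested).

What passing these benchmarks shows — and does not. The generators produce
clean Gaussian kinematics, isotropic noise, no segmentation errors, no
track fragmentation beyond configured gaps, and behaviour modes that are
stationary within a track. Real intravital data has none of these
guarantees: drift, photobleaching, mis-segmentation, track swaps and
behaviour switching within tracks will all erode the reported recovery
rates. The benchmarks validate the *machinery* (exactness of the dynamic
programs, correctness of the spatial operations against oracles, recovery
under the stated generative conditions), not field performance on any
particular dataset.

## Problem sizes and budgets

The shipped tests and the acceptance script run on one CPU in a few
minutes total. Chosen sizes: 50 random models for forward/Viterbi
enumeration checks (K ≤ 3, T ≤ 8); 200 sequences × 100 steps for 2-state
parameter recovery; 4 × 100 tracks × 60 steps × 5 seeds for the behaviour
pipeline; 2 × 150 cells for region recovery; ≤ 500-point random instances
for the spatial oracles; 10⁴ bins for the isotropic-flow limit. These sizes
are where the statistical tolerances (±0.1 on means, ±0.05 on transitions,
ARI ≥ 0.8/0.9, 3/√n) are comfortably met by a correct implementation and
missed by plausible bugs.

## Known limitations

* Delaunay is brute-force: quadratic-to-quartic, intended for
  hundreds of cells per field, not whole-slide millions.
* OME-Zarr reading is not implemented (no suitable R reader); TIFF and
  in-memory arrays are the label-image inputs.
* The greedy linker is not a probabilistic tracker; crossing or densely
  packed objects will swap identities.
* The contact fallback treats cells as volume-equivalent spheres; use
  surface samples for elongated cells.
* HMM emissions are diagonal Gaussians on z-scored features; heavy-tailed
  or multimodal within-state feature distributions are absorbed into extra
  states rather than modelled.
* `points_to_image()` rasterises 2D point clouds; 3D transcript volumes
  would need a 3D grid variant.
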