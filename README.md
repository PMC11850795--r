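# celltrax

Quantitative spatial and behavioural analysis of segmented multiplexed
microscopy images, as plain R functions on plain tibbles.

Modern tissue imaging produces two kinds of data that are awkward to analyse
together: **static multiplexed images** (confocal, IBEX, CODEX, Xenium) whose
segmented objects need population gating, neighbour analysis and niche
detection, and **time-lapse / intravital movies** whose tracked cells need
motility statistics and behaviour classification. `celltrax` covers the
computational core of both, downstream of segmentation: it consumes integer
label images and per-cell tables (one row per object per timepoint, centroids
in µm) and stays headless — every result is a tibble you can pipe onward.

## What it computes

**Spatial analysis of static images**

- Delaunay, radius and k-nearest neighbour graphs; closest-neighbour
  interaction partners per cell
- DBSCAN aggregate detection (default eps 20 µm, 4 cells)
- cellular-neighbourhood composition profiles (default radius 50 µm) and
  K-means region/niche detection; region-to-region interaction matrices
- exact nearest-distance to structure point clouds (vessels, stroma), cell–cell
  contacts by thresholded minimum separation (default 5 µm)
- hierarchical 2D histo-cytometry gating (boundary-inclusive even-odd
  point-in-polygon, optional `log10(v+1)` axes), rule-based populations
  (`tracked` ≡ `track_id > 0`)
- label-image utilities: merging of independently produced segmentations
  (first-wins priority with provenance), channel-division spill-over
  correction, per-object measurement (centroid, volume, mean intensities,
  gyration-tensor shape descriptors), transcript-point rasterisation by
  local box sums

**Behaviour analysis of tracked cells**

For a track with positions $x_t$ sampled every $\Delta t$, per-step speed
$v_t = \lVert x_{t+1}-x_t\rVert/\Delta t$ (µm/min) and unsigned turning angle
$\theta_t = \arccos(\hat d_{t-1}\cdot\hat d_t)$ feed a pooled $K$-state
Gaussian hidden Markov model

$$P(x, z) = \pi_{z_1}\prod_t A_{z_{t-1} z_t} \prod_t \mathcal N(x_t \mid \mu_{z_t}, \sigma^2_{z_t}),$$

fitted by Baum–Welch EM (diagonal covariances, z-scored features, seeded
restarts, monotone log-likelihood asserted) and decoded per track by Viterbi.
Each track is then summarised by its whole-track statistics (straightness =
net displacement / path length, speed summaries, turning angle, shape
means), its state occupancy vector and its observed state-transition
frequencies; the z-scored track × feature matrix is clustered by Leiden
community detection on a k-nearest-neighbour graph into behaviour clusters.
A 4-state shape HMM over gyration-tensor descriptors (asphericity,
prolateness, shape anisotropy $\kappa^2$, volume) captures morphodynamics the
same way. Collective motion is summarised by a binned mean-velocity flow
field whose nematic order parameter (leading eigenvalue of
$Q=\langle\hat u\hat u^\top\rangle - I/d$, scaled to $[0,1]$) scores
directional anisotropy.

**Simulators** generate ground-truthed tracks (persistent random walks across
four canonical phenotypes: directed, meandering, scanning, aggregating),
HMM sequences, tissue layouts and rasterised ellipsoids, so the entire test
surface is reproducible offline from seeds.

## Worked example

```r
library(celltrax)

sim    <- simulate_tracks(n_per_mode = 50, n_steps = 60, seed = 1)
steps  <- step_features(sim$cells, dt_seconds = 10)
model  <- fit_hmm(steps, K = 3, seed = 1)
model
#> <celltrax_hmm> 3 states on speed, turning_angle
#>   fitted on 11760 observations in 216 sequence(s); loglik -8507.135 (BIC 17201.7), 25 iteration(s)

states   <- decode_states(model, steps)
features <- assemble_behaviour_matrix(track_stats(steps), states)
clusters <- cluster_behaviours(features, seed = 1)
table(dplyr::inner_join(clusters, sim$truth, by = "track_id")[, c("behaviour_cluster", "mode")])
#>                  mode
#> behaviour_cluster aggregating directed meandering scanning
#>                 1           0       50          0        0
#>                 2           0        0         50        0
#>                 3           1        0          0       50
#>                 4          49        0          0        0
```

The three movement states separate slow/high-turning, intermediate and fast
persistent stepping; fusing their per-track occupancies and transitions with
track statistics recovers the four simulated behaviours almost perfectly
(adjusted Rand index 0.987 here). The same grammar handles niches in static
images:

```r
tissue  <- simulate_tissue(c(T_cell = 150, B_cell = 150), layout = "blobs", seed = 61)
regions <- tissue$cells |>
  neighbourhood_profiles(radius = 50, by = "population") |>
  kmeans_regions(R = 2, seed = 61)
adjusted_rand_index(regions$region, tissue$cells$region_truth)
#> [1] 1
```

`plot_tracks()`, `plot_regions()` and `autoplot()` (flow fields) give quick
ggplot views; `tidy()`/`glance()` expose fitted HMMs broom-style. A thin CLI
(`inst/cli/celltrax`) wraps the same functions for shell pipelines.

## Scope notes

Segmentation itself (Cellpose/Stardist/Mesmer), Bayesian tracking, GUI
interaction and mesh-based collision are out of scope: label images and
(optionally) track ids are inputs. The built-in greedy linker is plumbing for
data that arrives untracked, not a probabilistic tracker. Label images are
read from TIFF (or passed as arrays); see the methods vignette
(`vignettes/celltrax-methods.Rmd`) for the model assumptions, parameter
defaults and known limitations.
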