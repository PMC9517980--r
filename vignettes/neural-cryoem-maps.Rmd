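---
title: "Neural cryo-EM maps and density graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural cryo-EM maps and density graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cryo-EM map stores electron density on a discrete voxel grid, typically
with 0.5–1.5 Å spacing. Placing atoms requires density values — and density
*maxima* — at arbitrary points between voxel centres. Linear interpolation
cannot produce off-grid maxima: every tri-linear maximum sits on the grid,
and peaks are systematically flattened. This package represents a map as a
set of small sinusoidal neural networks (SIRENs), one per sub-region of the
grid, fitted so that the network reproduces the voxel samples and provides
a smooth, differentiable density field everywhere in between. On top of the
fitted field it extracts a *density graph*: local density peaks (candidate
atom or residue positions) found by gradient ascent, clustered into nodes
and connected by edges.

## The model

Each sub-region network is a fully connected perceptron with a sinusoidal
input layer, four hidden sinusoidal layers of 256 features, and a linear
output: a sine layer computes $y = \sin(\omega_0 (Wx + b))$ with
$\omega_0 = 30$. Weights are initialized uniformly in
$\pm\sqrt{6/n}$ for the first layer and $\pm\frac{1}{\omega_0}\sqrt{6/n}$
for all later layers ($n = 256$). This is the standard SIREN recipe: the
$1/\omega_0$ shrinkage of later-layer weights exactly offsets the
$\omega_0$ factor inside the sine, keeping pre-activation variance stable
through depth. We note for implementers that quoting the sine layer as
$\sin(Wx+b)$ *without* the $\omega_0$ factor, while keeping these bounds,
produces activations that decay by roughly $1/\omega_0$ per layer and a
network that cannot fit anything; the initialization bounds and the
$\omega_0$ forward factor are a matched pair, and the package implements
them as such.

### Normalization

Map densities are unitless and inconsistent between maps, so training
targets are normalized in two passes. First, non-positive densities are
clamped to zero and the rest scaled to $[0,1]$:
$d_1 = (d_0 - d_{\min}) / (d_{\max} - d_{\min})$ for $d_0 > 0$, else $0$,
where $d_{\min}$ is the minimum of the *clamped* map — i.e. zero whenever
any non-positive voxel exists. (Using the raw, possibly negative, minimum
would introduce a jump at $d_0 = 0$, defeating the clamp; the clamped
minimum keeps the transform continuous.) Second, $d_{train} = 2 d_1 - 1$
expands the range to $[-1,1]$, the natural output range of a sine network.
The mean $\mu$ and standard deviation $\sigma$ of $d_1$ are retained; they
set the graph seeding threshold later.

### Tiling

One fixed-size network cannot cover maps that range over orders of
magnitude in voxel count, so the grid is tiled into overlapping blocks of
at most 64 voxels per axis, overlapping neighbours by at least 4 voxels.
Per axis with $n_v$ voxels: region size $v_r = \min(n_v, 64)$, region
count $n_r = \lceil (n_v - v_r)/(v_r - 4) \rceil + 1$, spacing
$s = (n_v - v_r)/\max(n_r - 1, 1)$, and start indices
$i_n = \lfloor (n-1) s \rfloor$. The implementation re-checks coverage,
the 64-voxel cap and the 4-voxel overlap after planning and fails loudly
if any is violated; a property test exercises every $n_v$ from 1 to 2048.
Within each region, coordinates are rescaled per axis to $[-1,1]$ from the
region's voxel-centre bounds.

### Training

Each region trains against its voxels' $d_{train}$ values with MSE loss
and Adam. There are no validation splits — the point is to fit every
voxel. Training runs to the *natural fit point*: stop immediately once the
best loss $l_{\min} < 10^{-5}$, or after 25 epochs without improvement
while $10^{-5} \le l_{\min} < 4\times10^{-4}$. The weights achieving
$l_{\min}$ are checkpointed and returned (returning final-epoch weights
after a 25-epoch plateau would return a regressed fit). Choices the
training description leaves open, fixed here as package defaults:

* **learning rate** $10^{-4}$, Adam $\beta = (0.9, 0.999)$ — the SIREN
  reference defaults; configurable via `train_control()`.
* **epoch** = one pass over all region voxels. Regions up to 32,768 voxels
  train full-batch (the loss then belongs to exactly the weights being
  checkpointed); larger regions use shuffled mini-batches of 32,768, one
  pass counting as one epoch. The cap keeps peak memory for stored
  activations modest on ordinary hardware.
* **safety cap** of 20,000 epochs; reaching it returns the best weights
  with a warning rather than failing or silently succeeding.
* **precision**: weights and activations are float32, loss accumulation
  float64 — the exit thresholds are loss-scale sensitive.
* **bias initialization** uses the same uniform bound as the layer's
  weights (the reference implementation's convention).

Per-region seeds are `seed + region_index`, so results do not depend on
training order and regions could train concurrently.

### Querying and blending

A query point covered by a single region is answered by that region's
network. Where regions overlap along $k \ge 1$ axes, each overlapped axis
contributes a linear blend of the two flanking regions, weighted by the
coordinate's position across the overlap band, and the per-axis blends are
averaged. At a band edge the weight reaches 0 or 1 and the output reduces
to a single region's value, which makes the blended field continuous
across seams — a transect test guards this. When two or three axes overlap
at once, up to eight regions cover the point but the blending rule only
references two per axis; we evaluate exactly that rule, choosing the
earlier region on each overlapped axis as the base. Outputs are rescaled
from the internal $[-1,1]$ to a nominal $[0,1]$ and deliberately *not*
clamped: the fitted field may (and near sharp peaks should) exceed the
range of the training samples.

Gradients are computed by reverse-mode differentiation through the sine
layers, the region coordinate rescaling, *and* the blend weights (product
rule), so the gradient field is the exact derivative of the queried
density — which the peak-finding walk requires for consistency. Queries
outside the voxel-centre hull raise an error rather than returning zero;
the graph stage handles boundary exits explicitly.

## Density graphs

1. **Seeding.** A 0.5 Å lattice (aligned to the map origin) over the whole
   map, keeping points with density at least $T = \mu + 3\sigma$ (on the
   $d_1$ scale). A user-supplied raw contour value can replace $T$; it is
   converted through the stored normalization. The generic $\mu+3\sigma$
   rule needs no per-map tuning but, on noisy experimental maps, can seed
   noise or miss weak periphery — the trade-off the override exists for.
2. **Ascent.** Each seed moves in steps of 0.05 Å along its *unit*
   gradient direction (a raw-magnitude step would make a fixed "step size"
   meaningless), keeping the best density seen; the first non-improving
   step stops the walk. Steps leaving the map remove the seed. A
   zero-gradient start is its own peak; 10,000 iterations is the safety
   cap.
3. **Clustering.** Peaks within 0.2 Å are merged transitively (equivalent
   to DBSCAN with singleton clusters permitted); cluster centroids become
   candidate nodes, ordered lexicographically for determinism. The node's
   density feature is re-queried at the centroid.
4. **Edges.** Node pairs strictly closer than $2\times$ the map resolution
   are connected (ties at exactly the threshold excluded — documented,
   arbitrary); the edge feature is its length; isolated nodes are removed.

Node features are $(x, y, z, d)$; nothing else is available without map
annotation, and no further node filtering or refinement is applied by
design.

## The simulator and what it does (not) emulate

`simulate_map()` mimics molmap-style simulation: each atom contributes a
Gaussian $a\,e^{-r^2/2\sigma^2}$ with $\sigma = 0.225 \times$ resolution
(the molmap width convention), equal amplitudes by default
(element-weighted optional), on a grid of voxel size resolution/3 padded
by $\max(3\sigma, 3\,\text{Å})$, truncated at $5\sigma$ so empty regions
are exactly zero. `synthetic_structure()` grows a compact, self-avoiding
Cα walk (3.8 Å steps inside a sphere sized like a globular protein) with
approximate backbone satellites and alternating side-chain dummies —
enough geometry for simulation and matching studies, deterministic per
seed.

What passing tests on these fixtures show: the representation fits and
interpolates smooth Gaussian fields to below 0.01 MAE, recovers off-grid
peaks, and the graph machinery behaves per its contracts. What they do
*not* show: robustness to experimental noise, B-factor variation,
map-sharpening artifacts, or the contour-threshold sensitivity that real
EMDB depositions exhibit — the simulator produces noise-free maps by
construction.

A sampling caveat worth knowing: at the molmap default voxel size
(resolution/3, i.e. ~1.5σ), an *isolated* Gaussian is marginally sampled
and the fitted field develops a flat top whose argmax can sit several
tenths of an Ångström from the true centre, even when every training voxel
is reproduced to high accuracy. Peak-position studies in the test suite
therefore use voxels ≲ 0.75σ, the regime where atomic-resolution maps
actually operate; interpolation-MAE studies use the molmap default, where
the mass of control voxels lies on well-sampled flanks.

## Numerical choices and degenerate inputs

* Constant maps cannot be normalized (zero range) and are an error.
* Regions one voxel wide on an axis map that local coordinate to 0.
* Tri-linear queries clamp interior corner indices only to guard float
  round-off at the hull; genuinely outside points are errors.
* Matching uses greedy nearest-pair-first one-to-one assignment (sort
  candidate pairs by distance, accept when both endpoints free):
  deterministic and order-independent. An optimal maximum-cardinality mode
  exists for validation; on dispersed point sets the two agree, and the
  test suite tolerates (and counts) rare crafted-tie gaps.
* All randomness is seed-controlled; the structure generator and weight
  initializer save and restore R's RNG state.

## Problem sizes

The bundled studies are sized for a desk run: the interpolation study uses
a 20-residue structure at 3.0 Å (a ~25³-voxel training map, ~380k non-zero
control voxels), the seam study a 66-voxel-long two-region map, and the
graph studies single-Gaussian and 5-atom maps — a few minutes of training
each on one CPU core. The format itself has no such limits: tiling is
exercised to 2048 voxels per axis, and training cost scales linearly with
voxel count.

## Known limitations

* Interpolation quality is bounded by sampling: the format does not
  increase map resolution, it interpolates what the voxels determine.
* Edge thresholding at $2\times$ resolution is a heuristic; graphs from
  low-resolution maps connect residues, not atoms.
* The matching metrics treat "exclusive" pairing greedily; an adversarial
  tie construction can differ from the optimal assignment by a pair.
* Training at float32 makes bit-level reproducibility contingent on the
  BLAS; identical seeds on the same machine reproduce weights exactly.
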