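# neuralmap

Continuous, differentiable representations of cryo-EM density maps in R,
and a graph-based interpretation of them.

## The problem

Cryo-EM maps store electron density on a voxel grid (typically 0.5–1.5 Å
spacing), but building an atomic model needs density — and density
*maxima* — between voxel centres. Tri-linear interpolation cannot place a
maximum off the grid and systematically flattens peaks. `neuralmap`
instead fits a **neural cryo-EM map**: the voxel grid is tiled into
overlapping sub-regions of at most 64 voxels per axis (≥ 4-voxel overlap),
and each region is fitted by a small sinusoidal network (SIREN: layers
$y = \sin(\omega_0(Wx+b))$, four hidden layers of 256 features,
$\omega_0 = 30$) trained with Adam on the region's voxels, normalized to
$[-1,1]$, until the *natural fit point*: stop when the best MSE drops
below $10^{-5}$, or after 25 epochs without improvement while the best
MSE lies in $[10^{-5}, 4\times10^{-4})$. Region outputs are blended
linearly across overlaps, giving a density field $d(x,y,z)$ on a nominal
$[0,1]$ scale — continuous, differentiable, and deliberately not clamped
to the training range.

From the fitted field, a **density graph** is extracted: a 0.5 Å lattice
is thresholded at $T = \mu + 3\sigma$ of the normalized densities, the
surviving seeds walk uphill in 0.05 Å steps along the unit gradient until
a step no longer increases density, the resulting peaks are clustered
(0.2 Å neighbourhoods, singletons allowed), and cluster centroids become
nodes with features $(x, y, z, d)$, connected by edges shorter than twice
the map resolution (isolated nodes removed). At atomic resolution
(≲ 1.6 Å), nodes track individual atoms; at near-atomic resolution they
track residue locations.

The package also bundles everything needed to study the method without
external data: MRC/CCP4 input/output, a molmap-style Gaussian map
simulator, a deterministic generator of compact protein-like structures,
a tri-linear baseline, and evaluation utilities (interpolation MAE
against a fine control grid; exclusive node↔atom matching with
sensitivity, specificity and RMSD).

## Worked example

```r
library(neuralmap)

# a compact 20-residue synthetic structure, simulated at 3.0 A resolution
# (voxel = resolution/3), plus a fine 0.2 A control map
st   <- synthetic_structure(20, seed = 42)
map  <- simulate_map(st, simulation_spec(3.0))
ctrl <- simulate_map(st, simulation_spec(3.0, voxel_size = 0.2))

nm <- neural_map(map, seed = 1)     # ~3 min on one CPU core
interp_mae(nm, map, ctrl)
#> Interpolation error vs control map
#>   resolution    : 3 Angstrom
#>   MAE neural    : 0.007496
#>   MAE tri-linear: 0.01754
#>   control voxels: 382574 (non-zero)
```

The neural field reproduces the simulated ground truth at off-grid points
more than twice as accurately as the tri-linear baseline here (below 0.01
MAE on the normalized scale), and the gap widens as resolution worsens.
Graph extraction on an atomic-resolution fixture:

```r
pos <- rbind(c(0,0,0), c(1.9,0.6,0), c(3.8,0,0.4), c(5.7,0.6,0),
             c(7.6,0,-0.4))
at5 <- atom_set(rep("CA",5), "C", 1:5, "A", pos[,1], pos[,2], pos[,3])
m5  <- simulate_map(at5, simulation_spec(1.2, voxel_size = 0.6))
nm5 <- neural_map(m5, seed = 3)
g5  <- density_graph(nm5, resolution = 1.2)
match_nodes(g5, at5, radius = 1)
#> Node-to-atom match report (radius 1 Angstrom)
#>   matched pairs : 5 (of 5 atoms, 5 nodes)
#>   sensitivity   : 100.0% of atoms matched
#>   specificity   : 100.0% of nodes matched
#>   RMSD          : 0.185 Angstrom
```

Every atom is recovered by exactly one node, to sub-0.2 Å accuracy —
the regime expected from atomic-resolution maps.

`predict(nm, coords)` and `predict(nm, coords, type = "gradient")` query
the field directly; `resample(nm, 0.2)` writes it back onto a fine grid;
`write_mrc()` / `write_graph_json()` / `write_graphml()` export results.
A command-line wrapper with `simulate`, `train`, `query`, `resample`,
`graph`, `eval-interp`, `eval-graph` and `pipeline` subcommands is
installed at `system.file("cli", "neuralmap", package = "neuralmap")`.

## Method vignette

`vignettes/neural-cryoem-maps.Rmd` documents the model and its
assumptions, the tunable parameters and their defaults, what the
simulator does and does not emulate, numerical choices, and known
limitations.
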