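# Shared fixtures.  Trained neural maps are expensive, so each is built
# lazily once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, .fx_cache)) assign(name, builder(), .fx_cache)
  get(name, .fx_cache)
}

# Single Gaussian, well sampled (voxel 0.5 A, sigma 0.675 A).  The default
# padding aligns the atom with the voxel lattice, as molmap grids anchored
# at the bounding box do.
fx_gauss_centre <- c(0.17, -0.23, 0.11)
fx_gauss_sigma <- 0.675

fx_gauss_map <- function() fx("gauss_map", function() {
  at <- atom_set("CA", "C", 1, "A", fx_gauss_centre[1], fx_gauss_centre[2],
                 fx_gauss_centre[3])
  simulate_map(at, simulation_spec(3.0, voxel_size = 0.5, padding = 3))
})

fx_gauss_nmap <- function() fx("gauss_nmap", function() {
  neural_map(fx_gauss_map(), seed = 2)
})

# The same Gaussian sampled at the molmap-default voxel size (resolution/3
# = 2/3 A at 2 A resolution, i.e. ~1.5 voxels per sigma): deliberately
# marginal sampling, under which a faithful interpolant must swing above
# and below the voxel samples.
fx_gauss_coarse_nmap <- function() fx("gauss_coarse_nmap", function() {
  at <- atom_set("CA", "C", 1, "A", fx_gauss_centre[1], fx_gauss_centre[2],
                 fx_gauss_centre[3])
  m <- simulate_map(at, simulation_spec(2.0, voxel_size = 2 / 3,
                                        padding = 3))
  neural_map(m, seed = 2)
})

# Five atoms in a zig-zag chain ~2 A apart: peaks resolve at 1.2 A
# resolution and consecutive nodes fall under the 2.4 A edge threshold.
fx_chain_atoms <- function() {
  pos <- rbind(c(0, 0, 0), c(1.9, 0.6, 0), c(3.8, 0, 0.4),
               c(5.7, 0.6, 0), c(7.6, 0, -0.4))
  atom_set(rep("CA", 5), "C", 1:5, "A", pos[, 1], pos[, 2], pos[, 3])
}

fx_chain_nmap <- function() fx("chain_nmap", function() {
  m <- simulate_map(fx_chain_atoms(), simulation_spec(1.2, voxel_size = 0.6))
  neural_map(m, seed = 3)
})

# Long thin map forcing a 2-region tiling along x (66 voxels), with a row
# of Gaussians providing signal across the overlap band.
fx_seam_atoms <- function() {
  xs <- seq(4, 66, by = 5.3)
  atom_set(rep("CA", length(xs)), "C", seq_along(xs), "A", xs, 2.6, 2.6)
}

fx_seam_map <- function() fx("seam_map", function() {
  at <- fx_seam_atoms()
  spec <- simulation_spec(4.0, voxel_size = 1.0, padding = 3)
  m <- simulate_map(at, spec)
  stopifnot(m$shape[1] > 64)  # must tile into 2 regions along x
  m
})

fx_seam_nmap <- function() fx("seam_nmap", function() {
  neural_map(fx_seam_map(), seed = 5)
})

# Interpolation study fixture: a compact 20-residue synthetic structure
# simulated at 3.0 A resolution (voxel = resolution / 3) with a 0.2 A
# control grid.
fx_interp_structure <- function() fx("interp_structure", function() {
  synthetic_structure(20, seed = 42)
})

fx_interp_map <- function() fx("interp_map", function() {
  simulate_map(fx_interp_structure(), simulation_spec(3.0))
})

fx_interp_ctrl <- function() fx("interp_ctrl", function() {
  simulate_map(fx_interp_structure(), simulation_spec(3.0, voxel_size = 0.2))
})

fx_interp_nmap <- function(seed) fx(paste0("interp_nmap_", seed), function() {
  neural_map(fx_interp_map(), seed = seed)
})

# Linear ramp along x: analytic gradient (slope, 0, 0) on the normalized
# scale, and uphill walks from near the +x face leave the map.
fx_ramp_nmap <- function() fx("ramp_nmap", function() {
  nx <- 8L
  vals <- array(rep(seq(0, 7), 6 * 6), c(nx, 6L, 6L))
  m <- voxel_map(vals, voxel_size = 1)
  neural_map(m, seed = 6)
})

# ---- independent oracles ---------------------------------------------------

# Brute-force Gaussian sum (no truncation below the cutoff radius).
oracle_gaussian <- function(atoms, points, sigma, cutoff = Inf) {
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  vapply(seq_len(nrow(points)), function(q) {
    d2 <- rowSums(sweep(axyz, 2L, points[q, ], `-`)^2)
    sum(exp(-d2[d2 <= cutoff^2] / (2 * sigma^2)))
  }, numeric(1))
}

# Transitive closure of the eps-neighborhood relation, O(n^2).
oracle_cluster <- function(pts, eps) {
  n <- nrow(pts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          sum((pts[i, ] - pts[j, ])^2) <= eps^2) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), comp)
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting paths).
oracle_max_matching <- function(adj) {
  n_right <- ncol(adj)
  match_right <- rep(NA_integer_, n_right)
  matched <- 0L
  for (u0 in seq_len(nrow(adj))) {
    seen <- rep(FALSE, n_right)
    aug <- function(u) {
      for (v in which(adj[u, ])) {
        if (!seen[v]) {
          seen[v] <<- TRUE
          if (is.na(match_right[v]) || aug(match_right[v])) {
            match_right[v] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(u0)) matched <- matched + 1L
  }
  matched
}
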