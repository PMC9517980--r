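# Gaussian map simulation in the style of Chimera's molmap, plus a
# deterministic generator of compact protein-like test structures.

#' Map simulation settings
#'
#' Simulated maps are sums of resolution-dependent Gaussians centred on
#' atoms: each atom contributes `a * exp(-r^2 / (2 sigma^2))` with
#' `sigma = sigma_factor * resolution`. The default `sigma_factor` of 0.225
#' follows the molmap width convention (`1 / (pi * sqrt(2))`), and the
#' default voxel size of `resolution / 3` matches the voxel-to-resolution
#' ratio of typical experimental maps. Gaussians are truncated at
#' `cutoff_sigma` standard deviations so empty regions are exactly zero.
#'
#' @param resolution target map resolution in Angstrom.
#' @param voxel_size grid spacing in Angstrom (default `resolution / 3`).
#' @param sigma_factor Gaussian width as a fraction of the resolution.
#' @param padding Angstrom margin around the atom bounding box; must be at
#'   least `3 * sigma` (default `max(3 * sigma, 3)`).
#' @param amplitude_mode `"equal"` (all atoms weight 1) or `"element"`
#'   (weights proportional to atomic number).
#' @param cutoff_sigma truncation radius of each Gaussian, in sigmas.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(resolution, voxel_size = resolution / 3,
                            sigma_factor = 0.225,
                            padding = max(3 * sigma_factor * resolution, 3),
                            amplitude_mode = c("equal", "element"),
                            cutoff_sigma = 5) {
  stopifnot(resolution > 0, voxel_size > 0, cutoff_sigma > 0)
  sigma <- sigma_factor * resolution
  if (padding < 3 * sigma)
    stop("padding must be at least 3 * sigma = ", signif(3 * sigma, 4),
         " Angstrom")
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 sigma_factor = sigma_factor, sigma = sigma,
                 padding = padding,
                 amplitude_mode = match.arg(amplitude_mode),
                 cutoff_sigma = cutoff_sigma),
            class = "simulation_spec")
}

.atomic_number <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34)

#' Simulate a density map from an atom set
#'
#' Places a regular grid over the atom bounding box plus `spec$padding` and
#' fills every voxel with the sum of truncated atom-centred Gaussians.
#'
#' @param atoms an [atom_set()] with at least one atom.
#' @param spec a [simulation_spec()].
#' @return a [voxel_map()] with `resolution` set from the spec.
#' @export
simulate_map <- function(atoms, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!inherits(atoms, "atom_set") || nrow(atoms) == 0L)
    stop("simulate_map requires a non-empty atom_set")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min) - spec$padding
  hi <- apply(xyz, 2L, max) + spec$padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spec$voxel_size)) + 1L)
  amp <- if (spec$amplitude_mode == "equal") {
    rep(1, nrow(atoms))
  } else {
    z <- .atomic_number[toupper(atoms$element)]
    z[is.na(z)] <- 6  # unknown elements counted as carbon
    as.numeric(z)
  }
  vals <- cpp_gaussian_grid(xyz, amp, lo, rep(spec$voxel_size, 3L), dims,
                            spec$sigma, spec$cutoff_sigma * spec$sigma)
  voxel_map(array(vals, dim = dims), voxel_size = spec$voxel_size,
            origin = lo, resolution = spec$resolution)
}

#' Generate a compact protein-like structure
#'
#' Builds a deterministic, self-avoiding C-alpha walk with ~3.8 Angstrom
#' steps confined to a sphere sized for a globular protein, then decorates
#' each residue with backbone atoms (N, C, O) and, on alternating residues,
#' a side-chain dummy carbon. Intended as a stand-in for deposited
#' structures in tests and simulations; it reproduces chain geometry
#' coarsely (bond lengths are approximate) but respects the constraints
#' that matter downstream: consecutive C-alpha spacing in [3.7, 3.9]
#' Angstrom and no two atoms closer than 1 Angstrom.
#'
#' @param n_residues number of residues (>= 1).
#' @param seed integer seed; the same seed reproduces identical coordinates.
#' @return an [atom_set()].
#' @export
synthetic_structure <- function(n_residues, seed = 1) {
  stopifnot(n_residues >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  step <- 3.8
  min_sep <- 3.5  # non-consecutive C-alpha separation
  radius <- max(6, (3 * n_residues * 150 / (4 * pi))^(1 / 3))
  unit <- function(v) v / sqrt(sum(v^2))
  ca <- matrix(0, nrow = n_residues, ncol = 3L)
  dir <- unit(stats::rnorm(3L))
  if (n_residues > 1L) {
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in 1:200) {
        wobble <- 0.4 + 0.2 * try / 10
        cand_dir <- unit(dir + wobble * stats::rnorm(3L) -
                           0.05 * ca[i - 1L, ] / radius)
        cand <- ca[i - 1L, ] + step * cand_dir
        ok_sphere <- sqrt(sum(cand^2)) <= radius
        ok_avoid <- i <= 2L ||
          min(sqrt(rowSums(sweep(ca[1:(i - 2L), , drop = FALSE], 2L, cand,
                                 `-`)^2))) >= min_sep
        if (ok_sphere && ok_avoid) {
          ca[i, ] <- cand
          dir <- cand_dir
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("failed to place residue ", i, "; try another seed")
    }
  }

  # Local frames: tangent along the chain, normal parallel-transported for
  # smooth variation; satellites on unit directions >= 60 degrees apart with
  # offsets <= 1.35 A, so cross-residue clashes are geometrically excluded.
  ref <- unit(c(0.31, -0.52, 0.80))
  nrm_prev <- NULL
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    tang <- if (n_residues == 1L) {
      c(1, 0, 0)
    } else if (i < n_residues) {
      unit(ca[i + 1L, ] - ca[i, ])
    } else {
      unit(ca[i, ] - ca[i - 1L, ])
    }
    base <- if (is.null(nrm_prev)) ref else nrm_prev
    nrm <- base - sum(base * tang) * tang
    if (sqrt(sum(nrm^2)) < 1e-6) nrm <- ref - sum(ref * tang) * tang
    nrm <- unit(nrm)
    nrm_prev <- nrm
    bin <- c(tang[2] * nrm[3] - tang[3] * nrm[2],
             tang[3] * nrm[1] - tang[1] * nrm[3],
             tang[1] * nrm[2] - tang[2] * nrm[1])
    p_ca <- ca[i, ]
    p_n <- p_ca + 1.30 * unit(-tang + 0.45 * nrm)
    p_c <- p_ca + 1.30 * unit(tang + 0.45 * nrm)
    p_o <- p_ca + 1.35 * unit(tang - 0.9 * bin)
    pts <- rbind(N = p_n, CA = p_ca, C = p_c, O = p_o)
    if (i %% 2L == 0L)
      pts <- rbind(pts, CB = p_ca + 1.35 * unit(-nrm + 0.3 * bin))
    rows[[i]] <- data.frame(name = rownames(pts),
                            element = c("N", "C", "C", "O", "C")[
                              seq_len(nrow(pts))],
                            resno = i, x = pts[, 1], y = pts[, 2],
                            z = pts[, 3])
  }
  df <- do.call(rbind, rows)
  out <- atom_set(name = df$name, element = df$element, resno = df$resno,
                  chain = "A", x = df$x, y = df$y, z = df$z, resid = "ALA")
  d <- stats::dist(out[, c("x", "y", "z")])
  if (min(d) < 1.0)
    stop("internal error: generated atoms closer than 1 Angstrom")
  out
}
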