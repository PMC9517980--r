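test_that("tri-linear error vanishes when control equals input grid", {
  m <- fx_gauss_map()
  nm <- fx_gauss_nmap()
  rep <- interp_mae(nm, m, m)  # control voxels are input voxel centres
  expect_equal(rep$mae_trilinear, 0, tolerance = 1e-12)
  expect_lt(rep$mae_neural, 0.02)  # training reconstruction error only
  expect_equal(rep$n_voxels, sum(normalize_density(m)$d1 > 0))
})

test_that("interpolation error is invariant to global map rescaling", {
  m <- fx_gauss_map()
  nm <- fx_gauss_nmap()
  # rescaling both maps is absorbed by the [0,1] normalization
  m_scaled <- voxel_map(m$data * 7.3, m$voxel_size, m$origin)
  r1 <- interp_mae(nm, m, m)
  r2 <- interp_mae(nm, m_scaled, m_scaled)
  expect_equal(r1$mae_neural, r2$mae_neural, tolerance = 1e-12)
  expect_equal(r1$n_voxels, r2$n_voxels)
})

test_that("neural interpolation beats tri-linear on a fine control grid", {
  # canonical study conditions: voxel size = resolution / 3
  rep <- interp_mae(fx_interp_nmap(101), fx_interp_map(), fx_interp_ctrl())
  expect_lt(rep$mae_neural, rep$mae_trilinear)
  expect_gt(rep$n_voxels, 1000)
})

test_that("maps in disjoint frames are rejected", {
  m <- fx_gauss_map()
  nm <- fx_gauss_nmap()
  shifted <- voxel_map(m$data, m$voxel_size, m$origin + 100)
  expect_error(interp_mae(nm, m, shifted), "frame")
})

test_that("perfect node placement scores perfect metrics", {
  at <- synthetic_structure(3, seed = 2)
  nodes <- as.matrix(at[, c("x", "y", "z")])
  rep <- match_nodes(nodes, at, radius = 1)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$rmsd, 0, tolerance = 1e-6)
})

test_that("exclusive matching pairs each node and atom at most once", {
  at <- atom_set(c("CA", "CA"), "C", 1:2, "A", c(0, 0.7), 0, 0)
  rep <- match_nodes(matrix(c(0.3, 0, 0), 1), at, radius = 1)
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(rep$sensitivity, 50)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$pairs$atom, 1L)  # nearer atom wins
})

test_that("greedy matching achieves the optimal pair count on random sets", {
  set.seed(47)
  mismatches <- 0L
  for (trial in 1:100) {
    nodes <- matrix(runif(60, 0, 10), ncol = 3)
    atoms_xyz <- matrix(runif(60, 0, 10), ncol = 3)
    at <- atom_set(rep("CA", 20), "C", 1:20, "A", atoms_xyz[, 1],
                   atoms_xyz[, 2], atoms_xyz[, 3])
    greedy <- match_nodes(nodes, at, radius = 1)
    optimal <- match_nodes(nodes, at, radius = 1, method = "optimal")
    d <- sqrt(outer(rowSums(nodes^2), rowSums(atoms_xyz^2), `+`) -
                2 * tcrossprod(nodes, atoms_xyz))
    oracle <- oracle_max_matching(d <= 1)
    expect_equal(nrow(optimal$pairs), oracle)
    if (nrow(greedy$pairs) != oracle) mismatches <- mismatches + 1L
  }
  # nearest-first greedy matching is not guaranteed maximum-cardinality,
  # but on dispersed point sets it should essentially always be
  expect_lte(mismatches, 2L)
})

test_that("calpha-only matching restricts the atom set", {
  at <- synthetic_structure(4, seed = 3)
  ca <- as.matrix(at[at$is_calpha, c("x", "y", "z")])
  rep <- match_nodes(ca, at, radius = 3, calpha_only = TRUE)
  expect_equal(rep$n_atoms, 4L)
  expect_equal(rep$sensitivity, 100)
})

test_that("match metrics respond correctly to added nodes", {
  at <- synthetic_structure(5, seed = 9)
  axyz <- as.matrix(at[at$is_calpha, c("x", "y", "z")])
  base <- match_nodes(axyz[1:3, , drop = FALSE], at, radius = 1,
                      calpha_only = TRUE)
  # adding a node that matches a previously uncovered atom: sensitivity up
  more <- match_nodes(axyz[1:4, , drop = FALSE], at, radius = 1,
                      calpha_only = TRUE)
  expect_gte(more$sensitivity, base$sensitivity)
  # adding a far-away unmatched node: specificity strictly down
  noisy <- rbind(axyz[1:4, ], c(1000, 1000, 1000))
  worse <- match_nodes(noisy, at, radius = 1, calpha_only = TRUE)
  expect_equal(worse$sensitivity, more$sensitivity)
  expect_lt(worse$specificity, more$specificity)
})

test_that("empty inputs give zero metrics with a warning", {
  at <- synthetic_structure(2, seed = 5)
  expect_warning(rep <- match_nodes(matrix(numeric(), ncol = 3), at),
                 "empty")
  expect_equal(rep$sensitivity, 0)
  expect_equal(rep$specificity, 0)
  expect_true(is.na(rep$rmsd))
})
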