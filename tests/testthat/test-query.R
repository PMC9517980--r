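test_that("tri-linear interpolation reproduces voxel centres and edges", {
  vals <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  m <- voxel_map(vals, voxel_size = c(0.8, 1.0, 1.2), origin = c(1, 2, 3))
  # voxel centre: exact value
  expect_equal(trilinear(m, index_to_coord(m, c(2, 1, 3))),
               vals[3, 2, 4], tolerance = 1e-14)
  # midpoint of an edge between two voxels: their mean
  p <- (index_to_coord(m, c(0, 0, 0)) + index_to_coord(m, c(1, 0, 0))) / 2
  expect_equal(trilinear(m, p), mean(vals[1:2, 1, 1]), tolerance = 1e-14)
  # outside the voxel-centre hull: error
  expect_error(trilinear(m, c(0, 2, 3)), "outside")
})

test_that("tri-linear matches an independent 8-corner oracle", {
  vals <- array(runif(6 * 5 * 7), c(6, 5, 7))
  m <- voxel_map(vals, voxel_size = c(0.9, 1.1, 0.7), origin = c(-2, 0, 5))
  set.seed(17)
  b <- map_bounds(m)
  pts <- cbind(runif(1000, b[1, 1], b[1, 2]),
               runif(1000, b[2, 1], b[2, 2]),
               runif(1000, b[3, 1], b[3, 2]))
  got <- trilinear(m, pts)
  oracle <- vapply(seq_len(1000), function(q) {
    t <- (pts[q, ] - m$origin) / m$voxel_size
    i0 <- pmin(floor(t), m$shape - 2)
    f <- t - i0
    s <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- prod(ifelse(c(di, dj, dk) == 1, f, 1 - f))
      s <- s + w * vals[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1]
    }
    s
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-12)
})

test_that("tri-linear output is bounded by its corner values", {
  m <- fx_gauss_map()
  set.seed(23)
  b <- map_bounds(m)
  pts <- cbind(runif(200, b[1, 1], b[1, 2]), runif(200, b[2, 1], b[2, 2]),
               runif(200, b[3, 1], b[3, 2]))
  v <- trilinear(m, pts)
  expect_true(all(v <= max(m$data) + 1e-12))
  expect_true(all(v >= min(m$data) - 1e-12))
})

test_that("the neural field can leave the training value range", {
  # on a marginally sampled Gaussian the fitted field swings above the
  # largest voxel sample near the peak (and below zero in the background),
  # which a tri-linear interpolant by construction cannot do
  nm <- fx_gauss_coarse_nmap()
  local <- as.matrix(expand.grid(
    x = seq(fx_gauss_centre[1] - 1.5, fx_gauss_centre[1] + 1.5, 0.05),
    y = seq(fx_gauss_centre[2] - 1.5, fx_gauss_centre[2] + 1.5, 0.05),
    z = seq(fx_gauss_centre[3] - 1.5, fx_gauss_centre[3] + 1.5, 0.05)))
  expect_gt(max(predict(nm, local)), 1)  # training d1 is capped at 1
})

test_that("density queries outside the map bounds are errors", {
  nm <- fx_gauss_nmap()
  b <- map_bounds(neuralmap:::nmap_as_geometry(nm))
  expect_error(predict(nm, c(b[1, 2] + 1, 0, 0)), "outside")
  expect_error(predict(nm, c(0, 0, b[3, 1] - 0.01)), "outside")
  # in-bounds corner is fine
  expect_silent(predict(nm, b[, 1]))
})

test_that("single-region queries reduce to the rescaled network output", {
  nm <- fx_gauss_nmap()
  reg <- nm$regions[[1]]
  set.seed(41)
  pts <- cbind(runif(20, -2, 2), runif(20, -2, 2), runif(20, -2, 2))
  loc <- neuralmap:::region_local_coords(pts, reg$bounds)
  raw <- as.numeric(neuralmap:::cpp_siren_forward(reg$weights, t(loc),
                                                  nm$config$omega0))
  expect_equal(predict(nm, pts), (raw + 1) / 2, tolerance = 1e-12)
})

test_that("overlap blending follows the two-region weighted average", {
  nm <- fx_seam_nmap()
  ax <- nm$plan$axes[[1]]
  vs <- nm$voxel_size[1]
  lo2 <- nm$origin[1] + ax$starts[2] * vs             # overlap band start
  hi1 <- nm$origin[1] + (ax$starts[1] + ax$v_r - 1) * vs  # band end
  r1 <- nm$regions[[1]]; r2 <- nm$regions[[2]]
  eval_reg <- function(reg, pts) {
    loc <- neuralmap:::region_local_coords(pts, reg$bounds)
    as.numeric(neuralmap:::cpp_siren_forward(reg$weights, t(loc),
                                             nm$config$omega0))
  }
  set.seed(13)
  pts <- cbind(runif(100, lo2, hi1), runif(100, 1, 4), runif(100, 1, 4))
  w1 <- (hi1 - pts[, 1]) / (hi1 - lo2)
  oracle <- (w1 * eval_reg(r1, pts) + (1 - w1) * eval_reg(r2, pts) + 1) / 2
  expect_equal(predict(nm, pts), oracle, tolerance = 1e-5)
  # band edges collapse to a single region's output
  edge <- cbind(c(lo2, hi1), 2.5, 2.5)
  expect_equal(predict(nm, edge)[1], (eval_reg(r1, edge[1, , drop = FALSE])
                                      + 1) / 2, tolerance = 1e-5)
  expect_equal(predict(nm, edge)[2], (eval_reg(r2, edge[2, , drop = FALSE])
                                      + 1) / 2, tolerance = 1e-5)
})

test_that("the blended field is continuous across the region seam", {
  nm <- fx_seam_nmap()
  b <- map_bounds(neuralmap:::nmap_as_geometry(nm))
  xs <- seq(b[1, 1], b[1, 2], by = 0.01)
  d <- predict(nm, cbind(xs, 2.6, 2.6))
  jumps <- abs(diff(d))
  # no step between 0.01 A samples may exceed a smoothness threshold far
  # below the intra-map density variation (range ~1)
  expect_lt(max(jumps), 0.02)
})

test_that("analytic gradients agree with finite differences", {
  for (nm in list(fx_gauss_nmap(), fx_seam_nmap())) {
    b <- map_bounds(neuralmap:::nmap_as_geometry(nm))
    set.seed(29)
    pts <- cbind(runif(50, b[1, 1] + 0.1, b[1, 2] - 0.1),
                 runif(50, b[2, 1] + 0.1, b[2, 2] - 0.1),
                 runif(50, b[3, 1] + 0.1, b[3, 2] - 0.1))
    g <- predict(nm, pts, type = "gradient")
    h <- 1e-3
    for (a in 1:3) {
      e <- matrix(0, nrow(pts), 3)
      e[, a] <- h
      fd <- (predict(nm, pts + e) - predict(nm, pts - e)) / (2 * h)
      expect_lt(max(abs(g[, a] - fd)), 5e-3)
    }
  }
})

test_that("a ramp signal trains to a constant gradient along its axis", {
  nm <- fx_ramp_nmap()
  # normalized densities rise linearly from 0 to 1 over 7 A along x
  set.seed(43)
  pts <- cbind(runif(30, 1, 6), runif(30, 1, 4), runif(30, 1, 4))
  g <- predict(nm, pts, type = "gradient")
  # pointwise gradients wiggle between voxel samples (nothing constrains
  # the field off-grid), but on average the slope is recovered
  expect_equal(mean(g[, 1]), 1 / 7, tolerance = 0.15)
  expect_lt(abs(mean(g[, 2])), 0.05)
  expect_lt(abs(mean(g[, 3])), 0.05)
})

test_that("gradients vanish near a trained Gaussian peak", {
  nm <- fx_gauss_nmap()
  g0 <- sqrt(sum(predict(nm, fx_gauss_centre, type = "gradient")^2))
  g1 <- sqrt(sum(predict(nm, fx_gauss_centre + c(1, 0, 0),
                         type = "gradient")^2))
  expect_lt(g0, g1)
})

test_that("resampling honours the grid-shape contract", {
  nm <- fx_gauss_nmap()
  rs <- resample(nm, voxel_size = 0.9)
  extent <- (nm$shape - 1) * nm$voxel_size
  expect_equal(rs$shape, as.integer(floor(extent / 0.9)) + 1L)
  expect_equal(rs$origin, nm$origin)
  # native-spacing resample reproduces the normalized training data
  rs_native <- resample(nm, voxel_size = nm$voxel_size[1])
  d1 <- normalize_density(fx_gauss_map())$d1
  expect_lt(mean(abs(rs_native$data - d1)), 0.01)
  expect_error(resample(nm, 0.9, max_voxels = 10), "cap")
})
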