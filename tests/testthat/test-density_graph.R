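test_that("the seeding threshold is mean + 3 sd of the normalized data", {
  nm <- fx_gauss_nmap()
  expect_equal(neuralmap:::.seed_threshold(nm, seeding_config()),
               nm$norm$mean_d1 + 3 * nm$norm$sd_d1)
  # explicit override wins
  expect_equal(neuralmap:::.seed_threshold(nm, seeding_config(
    threshold = 0.25)), 0.25)
  # a raw map contour is converted through the normalization record
  thr <- neuralmap:::.seed_threshold(nm, seeding_config(contour = 0.5))
  expect_equal(thr, (0.5 - nm$norm$d_min) /
                 (nm$norm$d_max - nm$norm$d_min))
})

test_that("seeds concentrate inside the analytic iso-contour", {
  nm <- fx_gauss_nmap()
  sp <- seed_points(nm)
  expect_gt(nrow(sp), 0)
  thr <- neuralmap:::.seed_threshold(nm, seeding_config())
  # analytic radius where the normalized Gaussian crosses the threshold
  d_max <- nm$norm$d_max
  r_thr <- fx_gauss_sigma * sqrt(-2 * log(thr * d_max))
  d <- sqrt(rowSums(sweep(sp, 2, fx_gauss_centre, `-`)^2))
  expect_lt(max(d), r_thr + 0.35)  # interpolation-error margin
  # no seeds in the flat background
  expect_gt(min(nrow(sp)), 0)
})

test_that("seeding an all-background map warns and yields no seeds", {
  nm <- fx_gauss_nmap()
  expect_warning(sp <- seed_points(nm, seeding_config(threshold = 10)),
                 "no seed points")
  expect_equal(nrow(sp), 0L)
})

test_that("gradient ascent converges to the Gaussian centre", {
  nm <- fx_gauss_nmap()
  set.seed(19)
  seeds <- sweep(matrix(rnorm(30, 0, 0.3), ncol = 3), 2, fx_gauss_centre,
                 `+`)
  asc <- ascend_peaks(nm, seeds)
  expect_equal(nrow(asc$peaks), 10L)
  d <- sqrt(rowSums(sweep(asc$peaks, 2, fx_gauss_centre, `-`)^2))
  expect_lt(max(d), 0.05 + 0.05)  # within one ascent step of the optimum
  # ascent never decreases density below the seed's value
  expect_true(all(asc$density >= predict(nm, seeds)))
})

test_that("a seed at the peak is its own fixed point", {
  nm <- fx_gauss_nmap()
  set.seed(20)
  s0 <- sweep(matrix(rnorm(15, 0, 0.2), ncol = 3), 2, fx_gauss_centre, `+`)
  peak <- neuralmap:::cluster_peaks(ascend_peaks(nm, s0)$peaks)[1, ]
  again <- ascend_peaks(nm, matrix(peak, 1))
  expect_equal(again$peaks[1, ], peak, tolerance = 1e-12)
})

test_that("points driven over the map edge are removed from the pool", {
  # on a monotone ramp along x the uphill walk leaves through the +x face
  nm <- fx_ramp_nmap()
  seeds <- rbind(c(6.5, 2.5, 2.5), c(6.0, 3.0, 2.0))
  asc <- ascend_peaks(nm, seeds, ascent_config(max_iter = 2000))
  expect_equal(asc$exited, 2L)
  expect_equal(nrow(asc$peaks), 0L)
})

test_that("clustering matches the transitive-closure oracle", {
  set.seed(37)
  pts <- matrix(runif(150, 0, 2), ncol = 3)
  cents <- cluster_peaks(pts, eps = 0.2)
  comps <- oracle_cluster(pts, eps = 0.2)
  expect_equal(nrow(cents), length(comps))
  oracle_cents <- t(vapply(comps, function(ids) {
    colMeans(pts[ids, , drop = FALSE])
  }, numeric(3)))
  oracle_cents <- oracle_cents[order(oracle_cents[, 1], oracle_cents[, 2],
                                     oracle_cents[, 3]), , drop = FALSE]
  expect_equal(cents, oracle_cents, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("near and far peak pairs merge and separate correctly", {
  close_pair <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  expect_equal(cluster_peaks(close_pair), matrix(c(0.05, 0, 0), 1),
               ignore_attr = TRUE)
  far_pair <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(nrow(cluster_peaks(far_pair)), 2L)
  # singletons are their own clusters, not noise
  expect_equal(nrow(cluster_peaks(matrix(c(5, 5, 5), 1))), 1L)
  expect_equal(nrow(cluster_peaks(matrix(numeric(), ncol = 3))), 0L)
})

test_that("edges obey the 2 x resolution threshold and isolation rule", {
  nm <- fx_seam_nmap()  # long hull leaves room for the node layouts
  nodes <- rbind(c(10, 2.6, 2.6), c(13, 2.6, 2.6), c(10, 5.4, 3.1))
  g <- build_graph(nm, nodes, resolution = 2)
  # pairwise: 3.0 and ~2.84 below the 4 A threshold; 4.1 above it
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$length),
               sort(c(3, sqrt(2.8^2 + 0.5^2))), tolerance = 1e-12)
  # collinear nodes at 0, 3, 9 A along x with resolution 2: the far node
  # has no neighbour within 4 A and is removed
  g2 <- build_graph(nm, cbind(c(10, 13, 19), 2.6, 2.6), resolution = 2)
  expect_equal(nrow(g2$nodes), 2L)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$length, 3)
  # a single node has no edges and is removed
  g3 <- build_graph(nm, matrix(c(10, 2.6, 2.6), 1), resolution = 2)
  expect_equal(nrow(g3$nodes), 0L)
  # edge lengths equal the Euclidean node distance
  nd <- as.matrix(g$nodes[, c("x", "y", "z")])
  for (e in seq_len(nrow(g$edges))) {
    expect_equal(g$edges$length[e],
                 sqrt(sum((nd[g$edges$from[e], ] - nd[g$edges$to[e], ])^2)))
  }
})

test_that("the end-to-end graph recovers a 5-atom chain", {
  nm <- fx_chain_nmap()
  g <- density_graph(nm, resolution = 1.2)
  atoms <- fx_chain_atoms()
  expect_equal(nrow(g$nodes), 5L)
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  nd <- as.matrix(g$nodes[, c("x", "y", "z")])
  worst <- max(apply(nd, 1, function(p) {
    min(sqrt(rowSums(sweep(axyz, 2, p, `-`)^2)))
  }))
  expect_lt(worst, 0.2)
  # every node's density clears the seeding threshold
  thr <- g$provenance$seed_threshold
  expect_true(all(g$nodes$density >= thr))
  # deterministic: a second extraction is identical
  g2 <- density_graph(nm, resolution = 1.2)
  expect_identical(g$nodes, g2$nodes)
  expect_identical(g$edges, g2$edges)
})

test_that("node count decreases monotonically with the threshold", {
  nm <- fx_chain_nmap()
  thr0 <- neuralmap:::.seed_threshold(nm, seeding_config())
  counts <- vapply(c(thr0, 0.5, 0.95), function(th) {
    g <- density_graph(nm, resolution = 1.2,
                       seeding = seeding_config(threshold = th))
    nrow(g$nodes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("graphs export to igraph, JSON and GraphML", {
  nm <- fx_chain_nmap()
  g <- density_graph(nm, resolution = 1.2)
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(nrow(back$nodes), nrow(g$nodes))
  expect_equal(back$edges$length, g$edges$length)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gpath)
  expect_true(file.size(gpath) > 0)
})
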