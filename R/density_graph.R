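# Density-graph extraction: threshold-seeded lattice points are walked
# uphill along the density gradient to local peaks, clustered, and the
# cluster centroids connected by edges within twice the map resolution.

#' Seeding settings
#'
#' Seeds are laid on a regular lattice (aligned to the map origin) and kept
#' where the density reaches the threshold `T`. By default
#' `T = mean_d1 + 3 * sd_d1` from the map's normalization record; a raw map
#' contour value (e.g. an author-recommended contour) may be supplied
#' instead and is converted to the normalized scale.
#'
#' @param step lattice spacing in Angstrom.
#' @param threshold optional threshold on the normalized `[0, 1]` scale,
#'   overriding the default.
#' @param contour optional raw map contour value, normalized internally
#'   (ignored when `threshold` is given).
#' @return a `seeding_config` list.
#' @export
seeding_config <- function(step = 0.5, threshold = NULL, contour = NULL) {
  stopifnot(step > 0)
  structure(list(step = step, threshold = threshold, contour = contour),
            class = "seeding_config")
}

#' Gradient-ascent settings
#'
#' @param step ascent step length in Angstrom; each iteration moves a point
#'   by `step` along its unit gradient direction.
#' @param max_iter safety cap on iterations per seed.
#' @return an `ascent_config` list.
#' @export
ascent_config <- function(step = 0.05, max_iter = 10000L) {
  stopifnot(step > 0, max_iter >= 1L)
  structure(list(step = step, max_iter = as.integer(max_iter)),
            class = "ascent_config")
}

.seed_threshold <- function(nmap, cfg) {
  if (!is.null(cfg$threshold)) return(cfg$threshold)
  if (!is.null(cfg$contour)) return(normalize_value(nmap$norm, cfg$contour))
  nmap$norm$mean_d1 + 3 * nmap$norm$sd_d1
}

#' Seed points above the density threshold
#'
#' Samples the whole map on a lattice of `cfg$step` Angstrom and keeps the
#' points whose density reaches the seeding threshold.
#'
#' @param nmap a [neural_map()].
#' @param cfg a [seeding_config()].
#' @return N x 3 matrix of Angstrom coordinates (possibly zero rows, with a
#'   warning).
#' @export
seed_points <- function(nmap, cfg = seeding_config()) {
  stopifnot(inherits(nmap, "neural_map"))
  thr <- .seed_threshold(nmap, cfg)
  hull <- map_bounds(nmap_as_geometry(nmap))
  axes <- lapply(1:3, function(a) seq(hull[a, 1], hull[a, 2],
                                      by = cfg$step))
  grid <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]],
                                z = axes[[3]]))
  keep <- logical(nrow(grid))
  chunk <- 65536L
  for (lo in seq(1L, nrow(grid), by = chunk)) {
    hi <- min(nrow(grid), lo + chunk - 1L)
    keep[lo:hi] <- predict(nmap, grid[lo:hi, , drop = FALSE]) >= thr
  }
  out <- grid[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no seed points above threshold ", signif(thr, 4))
  out
}

# voxel_map-like geometry wrapper so map_bounds() works on a neural_map
nmap_as_geometry <- function(nmap) {
  structure(list(origin = nmap$origin, voxel_size = nmap$voxel_size,
                 shape = nmap$shape), class = "voxel_map")
}

#' Walk seed points uphill to density peaks
#'
#' Each point is iteratively moved by `cfg$step` Angstrom along its unit
#' gradient direction. The current position and density are retained each
#' iteration; on the first step that fails to increase the density the
#' point of highest density seen is returned. A step that would leave the
#' map removes the point from the pool. Points starting on a zero gradient
#' are their own peaks.
#'
#' @param nmap a [neural_map()].
#' @param seeds N x 3 matrix of in-bounds Angstrom coordinates.
#' @param cfg an [ascent_config()].
#' @return list with `peaks` (M x 3 matrix), `density` (length M),
#'   `exited` (count of points removed at the map boundary) and `capped`
#'   (count of points that hit the iteration cap; also raises a warning).
#' @export
ascend_peaks <- function(nmap, seeds, cfg = ascent_config()) {
  stopifnot(inherits(nmap, "neural_map"))
  seeds <- matrix(as.numeric(seeds), ncol = 3L)
  n <- nrow(seeds)
  if (n == 0L)
    return(list(peaks = seeds, density = numeric(), exited = 0L,
                capped = 0L))
  hull <- map_bounds(nmap_as_geometry(nmap))
  pos <- seeds
  dens <- predict(nmap, pos)
  status <- rep("active", n)
  iter <- 0L
  while (any(status == "active") && iter < cfg$max_iter) {
    iter <- iter + 1L
    act <- which(status == "active")
    g <- predict(nmap, pos[act, , drop = FALSE], type = "gradient")
    gn <- sqrt(rowSums(g^2))
    flat <- gn == 0
    if (any(flat)) status[act[flat]] <- "peak"
    act <- act[!flat]
    if (!length(act)) next
    g <- g[!flat, , drop = FALSE] / gn[!flat]
    cand <- pos[act, , drop = FALSE] + cfg$step * g
    oob <- cand[, 1] < hull[1, 1] | cand[, 1] > hull[1, 2] |
      cand[, 2] < hull[2, 1] | cand[, 2] > hull[2, 2] |
      cand[, 3] < hull[3, 1] | cand[, 3] > hull[3, 2]
    if (any(oob)) status[act[oob]] <- "exited"
    act <- act[!oob]
    if (!length(act)) next
    cand <- cand[!oob, , drop = FALSE]
    d_new <- predict(nmap, cand)
    up <- d_new > dens[act]
    pos[act[up], ] <- cand[up, , drop = FALSE]
    dens[act[up]] <- d_new[up]
    status[act[!up]] <- "peak"
  }
  capped <- sum(status == "active")
  if (capped > 0L)
    warning(capped, " point(s) hit the ascent iteration cap (",
            cfg$max_iter, "); returning best positions seen")
  keep <- status != "exited"
  list(peaks = pos[keep, , drop = FALSE], density = dens[keep],
       exited = sum(status == "exited"), capped = capped)
}

#' Cluster peaks into candidate nodes
#'
#' Density-based clustering with neighborhood radius `eps` and singleton
#' clusters permitted (a point with no neighbor within `eps` is its own
#' cluster), i.e. the clusters are the connected components of the
#' `eps`-neighborhood graph. Implemented with spatial hashing and
#' union-find; cluster order is deterministic (lexicographic by centroid).
#'
#' @param peaks N x 3 matrix of Angstrom coordinates.
#' @param eps neighborhood radius in Angstrom.
#' @return M x 3 matrix of cluster centroids.
#' @export
cluster_peaks <- function(peaks, eps = 0.2) {
  peaks <- matrix(as.numeric(peaks), ncol = 3L)
  n <- nrow(peaks)
  if (n == 0L) return(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  cell <- floor(sweep(peaks, 2L, eps, `/`))
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in names(buckets)) {
    ids <- buckets[[b]]
    c0 <- cell[ids[1L], ]
    neigh <- integer()
    for (o in seq_len(nrow(offs))) {
      k <- paste(c0[1] + offs[o, 1], c0[2] + offs[o, 2],
                 c0[3] + offs[o, 3], sep = ",")
      nb <- buckets[[k]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (i in ids) {
      d2 <- rowSums(sweep(peaks[neigh, , drop = FALSE], 2L, peaks[i, ],
                          `-`)^2)
      for (j in neigh[d2 <= eps^2]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  cents <- t(vapply(split(seq_len(n), comp), function(ids) {
    colMeans(peaks[ids, , drop = FALSE])
  }, numeric(3)))
  cents[order(cents[, 1], cents[, 2], cents[, 3]), , drop = FALSE]
}

#' Assemble a density graph from candidate nodes
#'
#' Connects every node pair closer than `2 * resolution` Angstrom with an
#' edge whose feature is its length, attaches the map density at each node,
#' and removes isolated nodes.
#'
#' @param nmap a [neural_map()].
#' @param nodes M x 3 matrix of node coordinates (cluster centroids).
#' @param resolution map resolution in Angstrom (defaults to the neural
#'   map's stored resolution).
#' @return an object of class `density_graph` with `nodes`
#'   (`id`, `x`, `y`, `z`, `density`), `edges` (`from`, `to`, `length`) and
#'   a `provenance` list.
#' @export
build_graph <- function(nmap, nodes, resolution = nmap$resolution) {
  stopifnot(inherits(nmap, "neural_map"))
  if (is.null(resolution) || resolution <= 0)
    stop("a positive map resolution is required to build edges")
  nodes <- matrix(as.numeric(nodes), ncol = 3L)
  thr <- 2 * resolution
  if (nrow(nodes) == 0L) {
    return(.density_graph(data.frame(id = integer(), x = numeric(),
                                     y = numeric(), z = numeric(),
                                     density = numeric()),
                          data.frame(from = integer(), to = integer(),
                                     length = numeric()),
                          nmap, resolution))
  }
  d <- as.matrix(stats::dist(nodes))
  adj <- d < thr & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  deg <- integer(nrow(nodes))
  if (nrow(idx)) {
    tab <- table(factor(c(idx[, 1], idx[, 2]),
                        levels = seq_len(nrow(nodes))))
    deg <- as.integer(tab)
  }
  keep <- which(deg > 0L)
  remap <- integer(nrow(nodes))
  remap[keep] <- seq_along(keep)
  nodes_kept <- nodes[keep, , drop = FALSE]
  dens <- if (nrow(nodes_kept)) predict(nmap, nodes_kept) else numeric()
  nd <- data.frame(id = seq_along(keep), x = nodes_kept[, 1],
                   y = nodes_kept[, 2], z = nodes_kept[, 3],
                   density = dens)
  ed <- if (nrow(idx)) {
    data.frame(from = remap[idx[, 1]], to = remap[idx[, 2]],
               length = d[idx])
  } else {
    data.frame(from = integer(), to = integer(), length = numeric())
  }
  .density_graph(nd, ed, nmap, resolution)
}

.density_graph <- function(nodes, edges, nmap, resolution,
                           threshold = NA_real_) {
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(resolution = resolution,
                                   edge_threshold = 2 * resolution,
                                   seed_threshold = threshold,
                                   map_shape = nmap$shape,
                                   map_origin = nmap$origin)),
            class = "density_graph")
}

#' Extract a density graph from a neural map
#'
#' Full pipeline: lattice seeding above the threshold, gradient ascent to
#' peaks (boundary exits dropped), clustering at `eps = 0.2` Angstrom, and
#' edge construction below `2 * resolution`. Deterministic for a given
#' fitted map.
#'
#' @param nmap a [neural_map()].
#' @param resolution map resolution in Angstrom (defaults to the stored
#'   one).
#' @param seeding a [seeding_config()].
#' @param ascent an [ascent_config()].
#' @param eps clustering neighborhood radius in Angstrom.
#' @return a `density_graph`.
#' @export
density_graph <- function(nmap, resolution = nmap$resolution,
                          seeding = seeding_config(),
                          ascent = ascent_config(), eps = 0.2) {
  seeds <- seed_points(nmap, seeding)
  asc <- ascend_peaks(nmap, seeds, ascent)
  cents <- cluster_peaks(asc$peaks, eps = eps)
  g <- build_graph(nmap, cents, resolution = resolution)
  g$provenance$seed_threshold <- .seed_threshold(nmap, seeding)
  g$provenance$n_seeds <- nrow(seeds)
  g$provenance$n_exited <- asc$exited
  g
}

#' @export
print.density_graph <- function(x, ...) {
  cat("Cryo-EM density graph\n")
  cat("  nodes :", nrow(x$nodes), "\n")
  cat("  edges :", nrow(x$edges), "\n")
  if (!is.null(x$provenance$resolution))
    cat("  edge threshold :", x$provenance$edge_threshold, "Angstrom (2 x ",
        x$provenance$resolution, "Angstrom resolution)\n")
  if (!is.na(x$provenance$seed_threshold %||% NA))
    cat("  seed threshold :", signif(x$provenance$seed_threshold, 4),
        "(normalized density)\n")
  invisible(x)
}

#' Convert a density graph to igraph
#'
#' @param graph a `density_graph`.
#' @return an [igraph::graph] with node attributes `x`, `y`, `z`,
#'   `density` and edge attribute `length`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "density_graph"))
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = graph$nodes[, c("id", "x", "y", "z", "density")])
}

#' Export a density graph
#'
#' `write_graph_json` writes nodes (`id,x,y,z,density`) and edges
#' (`from,to,length`) as JSON; `write_graphml` writes GraphML via igraph.
#'
#' @param graph a `density_graph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "density_graph"))
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges,
                            provenance = graph$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
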