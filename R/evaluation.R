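# Evaluation protocols: interpolation accuracy against a fine control grid,
# and one-to-one matching of graph nodes to atoms.

#' Interpolation error against a control map
#'
#' Both maps are normalized independently to `[0, 1]` (clamp-and-scale
#' first pass). The neural map and the tri-linear interpolation of the
#' input map are then evaluated at the Angstrom centres of every control
#' voxel with a non-zero control value (restricting to non-zero voxels
#' keeps the neural format's small global background error out of the
#' comparison), and the mean absolute error of each interpolator against
#' the control value is reported. Control voxels outside the input map's
#' voxel-centre hull are excluded.
#'
#' @param nmap a [neural_map()] fitted to `input_map`.
#' @param input_map the training-resolution [voxel_map()].
#' @param control_map the fine control [voxel_map()] (typically 0.2
#'   Angstrom voxels) simulated in the same spatial frame.
#' @return an `interp_report` with `mae_neural`, `mae_trilinear` and
#'   `n_voxels`.
#' @export
interp_mae <- function(nmap, input_map, control_map) {
  stopifnot(inherits(nmap, "neural_map"), inherits(input_map, "voxel_map"),
            inherits(control_map, "voxel_map"))
  overlap <- pmin(map_bounds(input_map)[, 2],
                  map_bounds(control_map)[, 2]) -
    pmax(map_bounds(input_map)[, 1], map_bounds(control_map)[, 1])
  if (any(overlap <= 0))
    stop("input and control maps do not share a spatial frame")
  in_norm <- normalize_density(input_map)$d1
  ctrl_norm <- normalize_density(control_map)$d1

  nz <- which(ctrl_norm > 0)
  dims <- control_map$shape
  ijk <- cbind((nz - 1L) %% dims[1],
               ((nz - 1L) %/% dims[1]) %% dims[2],
               (nz - 1L) %/% (dims[1] * dims[2]))
  centres <- index_to_coord(control_map, ijk)
  hull <- map_bounds(input_map)
  inside <- centres[, 1] >= hull[1, 1] & centres[, 1] <= hull[1, 2] &
    centres[, 2] >= hull[2, 1] & centres[, 2] <= hull[2, 2] &
    centres[, 3] >= hull[3, 1] & centres[, 3] <= hull[3, 2]
  centres <- centres[inside, , drop = FALSE]
  truth <- ctrl_norm[nz[inside]]

  abs_n <- 0; abs_t <- 0
  chunk <- 65536L
  n_used <- nrow(centres)
  for (lo in seq(1L, n_used, by = chunk)) {
    hi <- min(n_used, lo + chunk - 1L)
    cc <- centres[lo:hi, , drop = FALSE]
    abs_n <- abs_n + sum(abs(predict(nmap, cc) - truth[lo:hi]))
    abs_t <- abs_t + sum(abs(trilinear(input_map, cc, values = in_norm) -
                               truth[lo:hi]))
  }
  structure(list(mae_neural = abs_n / n_used,
                 mae_trilinear = abs_t / n_used,
                 n_voxels = n_used,
                 resolution = input_map$resolution),
            class = "interp_report")
}

#' @export
print.interp_report <- function(x, ...) {
  cat("Interpolation error vs control map\n")
  if (!is.null(x$resolution))
    cat("  resolution    :", x$resolution, "Angstrom\n")
  cat("  MAE neural    :", signif(x$mae_neural, 4), "\n")
  cat("  MAE tri-linear:", signif(x$mae_trilinear, 4), "\n")
  cat("  control voxels:", x$n_voxels, "(non-zero)\n")
  invisible(x)
}

#' Match graph nodes to atoms
#'
#' One-to-one ("exclusive") matching of nodes to atoms within `radius`
#' Angstrom. The default greedy strategy sorts all candidate pairs by
#' ascending distance and accepts a pair when both endpoints are still
#' free; the `"optimal"` mode computes a maximum-cardinality matching of
#' the distance-thresholded bipartite graph instead. Sensitivity is the
#' percentage of atoms matched, specificity the percentage of nodes
#' matched, and RMSD the root mean squared distance over matched pairs.
#'
#' @param graph a `density_graph`, or an N x 3 matrix of node coordinates.
#' @param atoms an [atom_set()].
#' @param radius matching radius in Angstrom.
#' @param calpha_only restrict the atoms to alpha carbons (residue-level
#'   evaluation; conventionally used with `radius = 3`).
#' @param method `"greedy"` or `"optimal"`.
#' @return a `match_report` with `pairs` (data frame `node`, `atom`,
#'   `distance`), `sensitivity`, `specificity`, `rmsd`, `n_atoms`,
#'   `n_nodes`, `radius`.
#' @export
match_nodes <- function(graph, atoms, radius = 1, calpha_only = FALSE,
                        method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(radius > 0, inherits(atoms, "atom_set"))
  nodes <- if (inherits(graph, "density_graph")) {
    as.matrix(graph$nodes[, c("x", "y", "z")])
  } else {
    matrix(as.numeric(graph), ncol = 3L)
  }
  if (calpha_only) atoms <- atoms[atoms$is_calpha, , drop = FALSE]
  axyz <- as.matrix(atoms[, c("x", "y", "z")])
  n_nodes <- nrow(nodes); n_atoms <- nrow(axyz)
  if (n_nodes == 0L || n_atoms == 0L) {
    warning("empty ", if (n_nodes == 0L) "node" else "atom",
            " set; metrics are zero")
    return(.match_report(data.frame(node = integer(), atom = integer(),
                                    distance = numeric()),
                         n_atoms, n_nodes, radius))
  }
  dmat <- sqrt(pmax(outer(rowSums(nodes^2), rowSums(axyz^2), `+`) -
                      2 * tcrossprod(nodes, axyz), 0))
  cand <- which(dmat <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(.match_report(data.frame(node = integer(), atom = integer(),
                                    distance = numeric()),
                         n_atoms, n_nodes, radius))
  cd <- dmat[cand]
  if (method == "greedy") {
    ord <- order(cd, cand[, 1], cand[, 2])
    node_free <- rep(TRUE, n_nodes)
    atom_free <- rep(TRUE, n_atoms)
    sel <- logical(length(ord))
    for (q in seq_along(ord)) {
      i <- cand[ord[q], 1]; j <- cand[ord[q], 2]
      if (node_free[i] && atom_free[j]) {
        sel[q] <- TRUE
        node_free[i] <- FALSE
        atom_free[j] <- FALSE
      }
    }
    picked <- ord[sel]
    pairs <- data.frame(node = cand[picked, 1], atom = cand[picked, 2],
                        distance = cd[picked])
  } else {
    types <- c(rep(FALSE, n_nodes), rep(TRUE, n_atoms))
    g <- igraph::graph_from_edgelist(
      cbind(cand[, 1], n_nodes + cand[, 2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_nodes + n_atoms -
                                       igraph::vcount(g)))
    igraph::V(g)$type <- types
    m <- igraph::max_bipartite_match(g)$matching
    node_match <- m[seq_len(n_nodes)]
    keep <- which(!is.na(node_match))
    atom_idx <- as.integer(node_match[keep]) - n_nodes
    pairs <- data.frame(node = keep, atom = atom_idx,
                        distance = dmat[cbind(keep, atom_idx)])
  }
  .match_report(pairs, n_atoms, n_nodes, radius)
}

.match_report <- function(pairs, n_atoms, n_nodes, radius) {
  structure(list(pairs = pairs,
                 sensitivity = if (n_atoms) 100 * nrow(pairs) / n_atoms
                               else 0,
                 specificity = if (n_nodes) 100 * nrow(pairs) / n_nodes
                               else 0,
                 rmsd = if (nrow(pairs)) sqrt(mean(pairs$distance^2))
                        else NA_real_,
                 n_atoms = n_atoms, n_nodes = n_nodes, radius = radius),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("Node-to-atom match report (radius ", x$radius, " Angstrom)\n",
      sep = "")
  cat(sprintf("  matched pairs : %d (of %d atoms, %d nodes)\n",
              nrow(x$pairs), x$n_atoms, x$n_nodes))
  cat(sprintf("  sensitivity   : %.1f%% of atoms matched\n",
              x$sensitivity))
  cat(sprintf("  specificity   : %.1f%% of nodes matched\n",
              x$specificity))
  if (!is.na(x$rmsd))
    cat(sprintf("  RMSD          : %.3f Angstrom\n", x$rmsd))
  invisible(x)
}
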