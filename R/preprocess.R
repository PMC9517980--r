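# Density normalization and the overlapping sub-region tiling of the voxel
# grid that one network is trained on per region.

#' Two-pass density normalization
#'
#' First pass: non-positive densities are clamped to zero and the remaining
#' values scaled to `[0, 1]` as `(d0 - d_min) / (d_max - d_min)`, where
#' `d_min` is the minimum of the clamped map (zero whenever any non-positive
#' voxel exists, keeping the transform continuous at zero). Second pass:
#' `d_train = 2 * d1 - 1` expands the range to `[-1, 1]` for network
#' training. The mean and standard deviation of the first-pass values are
#' retained; they define the default seeding threshold `mu + 3 sigma` used
#' in graph extraction.
#'
#' @param map a [voxel_map()] with at least two distinct values and at
#'   least one positive value.
#' @return list with `d1` (array on the `[0, 1]` scale), `d_train` (array
#'   on the `[-1, 1]` scale) and `record`, a `norm_record` holding `d_min`,
#'   `d_max`, `mean_d1`, `sd_d1`.
#' @export
normalize_density <- function(map) {
  stopifnot(inherits(map, "voxel_map"))
  d0 <- map$data
  clamped <- pmax(d0, 0)
  d_min <- min(clamped)
  d_max <- max(d0)
  if (d_max <= d_min)
    stop("cannot normalize a map with no density range (min = max = ",
         signif(d_max, 6), ")")
  d1 <- array(0, dim = dim(d0))
  pos <- d0 > 0
  d1[pos] <- (d0[pos] - d_min) / (d_max - d_min)
  record <- structure(list(d_min = d_min, d_max = d_max,
                           mean_d1 = mean(d1), sd_d1 = stats::sd(d1)),
                      class = "norm_record")
  list(d1 = d1, d_train = 2 * d1 - 1, record = record)
}

# Raw map value -> first-pass normalized scale (used for user-supplied
# contour thresholds).
normalize_value <- function(record, value) {
  pmax(0, (value - record$d_min) / (record$d_max - record$d_min))
}

.axis_tiling <- function(n_v, max_len = 64L, min_overlap = 4L) {
  v_r <- if (n_v < max_len) n_v else max_len
  n_r <- if (n_v == v_r) 1L else
    as.integer(ceiling((n_v - v_r) / (v_r - min_overlap))) + 1L
  s <- (n_v - v_r) / max(n_r - 1L, 1L)
  starts <- floor((seq_len(n_r) - 1L) * s)
  list(n_v = as.integer(n_v), v_r = as.integer(v_r), n_r = n_r, s = s,
       starts = as.integer(starts))
}

#' Plan the sub-region tiling of a voxel grid
#'
#' Splits each axis into windows of at most 64 voxels that overlap adjacent
#' windows by at least 4 voxels. Per axis with `n_v` voxels the region size
#' is `v_r = min(n_v, 64)`, the region count
#' `n_r = ceil((n_v - v_r) / (v_r - 4)) + 1`, the spacing
#' `s = (n_v - v_r) / max(n_r - 1, 1)`, and the 0-based start indices
#' `floor((n - 1) * s)` for `n = 1..n_r`. Regions are the Cartesian product
#' of the per-axis windows. Coverage, the size cap and the overlap
#' guarantee are re-checked and violations raise an error.
#'
#' @param shape integer length-3 voxel counts.
#' @return a `tiling_plan`: per-axis parameters plus a list of regions,
#'   each a 3 x 2 matrix of 0-based `[start, end)` index ranges.
#' @export
plan_tiling <- function(shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  axes <- lapply(shape, .axis_tiling)
  for (a in 1:3) {
    ax <- axes[[a]]
    if (ax$v_r > 64L) stop("region size exceeds 64 voxels on axis ", a)
    if (ax$starts[ax$n_r] + ax$v_r != ax$n_v)
      stop("tiling does not cover axis ", a)
    if (ax$n_r > 1L) {
      ov <- ax$starts[-ax$n_r] + ax$v_r - ax$starts[-1L]
      if (any(ov < 4L)) stop("tiling overlap below 4 voxels on axis ", a)
    }
  }
  idx <- expand.grid(i = seq_along(axes[[1]]$starts),
                     j = seq_along(axes[[2]]$starts),
                     k = seq_along(axes[[3]]$starts))
  regions <- lapply(seq_len(nrow(idx)), function(r) {
    st <- c(axes[[1]]$starts[idx$i[r]], axes[[2]]$starts[idx$j[r]],
            axes[[3]]$starts[idx$k[r]])
    vr <- c(axes[[1]]$v_r, axes[[2]]$v_r, axes[[3]]$v_r)
    m <- cbind(start = st, end = st + vr)
    attr(m, "axis_index") <- c(idx$i[r], idx$j[r], idx$k[r])
    m
  })
  structure(list(axes = axes, regions = regions, shape = shape),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat("Sub-region tiling plan\n")
  cat("  grid   :", paste(x$shape, collapse = " x "), "voxels\n")
  for (a in 1:3) {
    ax <- x$axes[[a]]
    cat(sprintf("  axis %d : %d region(s) of %d voxels, starts [%s]\n",
                a, ax$n_r, ax$v_r, paste(ax$starts, collapse = ", ")))
  }
  cat("  total  :", length(x$regions), "region(s)\n")
  invisible(x)
}

# Angstrom voxel-centre bounds of a region (3 x 2), given map geometry.
region_bounds <- function(region, origin, voxel_size) {
  cbind(origin + region[, "start"] * voxel_size,
        origin + (region[, "end"] - 1L) * voxel_size)
}

# Map Angstrom coordinates (N x 3) to a region's local [-1, 1] cube.
# Degenerate single-voxel axes map to 0.
region_local_coords <- function(coords, bounds) {
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  span <- hi - lo
  out <- matrix(0, nrow = nrow(coords), ncol = 3L)
  for (a in 1:3) {
    out[, a] <- if (span[a] > 0)
      2 * (coords[, a] - lo[a]) / span[a] - 1 else 0
  }
  out
}
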