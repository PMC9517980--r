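# Continuous density and gradient retrieval from a fitted neural map, with
# overlap-weighted blending of the per-region networks, plus the tri-linear
# baseline interpolator and grid resampling.

# Per-axis blend bookkeeping for a batch of points.  For each axis: the
# covering slab pair (k1 earlier, k2 later), whether the point lies in the
# overlap band, and the blend weight w1 = (hi_k1 - p) / (hi_k1 - lo_k2).
.axis_blend <- function(nmap, p, axis) {
  ax <- nmap$plan$axes[[axis]]
  lo <- nmap$origin[axis] + ax$starts * nmap$voxel_size[axis]
  hi <- nmap$origin[axis] +
    (ax$starts + ax$v_r - 1L) * nmap$voxel_size[axis]
  k_hi <- pmin(pmax(findInterval(p, lo), 1L), ax$n_r)
  in_ov <- k_hi > 1L & p <= hi[pmax(k_hi - 1L, 1L)]
  k1 <- ifelse(in_ov, k_hi - 1L, k_hi)
  w1 <- rep(1, length(p))
  dw1 <- rep(0, length(p))
  if (any(in_ov)) {
    span <- hi[k1[in_ov]] - lo[k_hi[in_ov]]
    w1[in_ov] <- (hi[k1[in_ov]] - p[in_ov]) / span
    dw1[in_ov] <- -1 / span
  }
  list(k1 = k1, k2 = k_hi, in_ov = in_ov, w1 = w1, dw1 = dw1)
}

# Flat region index from per-axis slab indices (axis 1 fastest, matching
# the expand.grid order used by plan_tiling).
.region_index <- function(nmap, i, j, k) {
  n1 <- nmap$plan$axes[[1]]$n_r
  n2 <- nmap$plan$axes[[2]]$n_r
  i + n1 * ((j - 1L) + n2 * (k - 1L))
}

# Evaluate one region's network at Angstrom coordinates (rows of `coords`),
# optionally with the gradient in Angstrom units (chain rule through the
# region's local [-1, 1] scaling applied here).
.region_eval <- function(nmap, r, coords, gradient = FALSE) {
  reg <- nmap$regions[[r]]
  local <- region_local_coords(coords, reg$bounds)
  out <- list(value = as.numeric(
    cpp_siren_forward(reg$weights, t(local), nmap$config$omega0)))
  if (gradient) {
    g <- t(cpp_siren_input_grad(reg$weights, t(local),
                                nmap$config$omega0))
    span <- reg$bounds[, 2L] - reg$bounds[, 1L]
    scale <- ifelse(span > 0, 2 / span, 0)
    out$grad <- sweep(g, 2L, scale, `*`)
  }
  out
}

# Blended network output (internal [-1, 1] scale) and optionally its exact
# Angstrom-space gradient, including the derivative of the blend weights.
.nm_eval <- function(nmap, coords, gradient = FALSE) {
  n_pts <- nrow(coords)
  ab <- lapply(1:3, function(a) .axis_blend(nmap, coords[, a], a))
  base_r <- .region_index(nmap, ab[[1]]$k1, ab[[2]]$k1, ab[[3]]$k1)
  n_ov <- ab[[1]]$in_ov + ab[[2]]$in_ov + ab[[3]]$in_ov

  # Evaluation requests: base region for every point, plus the axis-switched
  # region for every overlapped axis.  Batched per region.
  req_point <- list(seq_len(n_pts))
  req_region <- list(base_r)
  req_slot <- list(rep(0L, n_pts))
  for (a in 1:3) {
    sel <- which(ab[[a]]$in_ov)
    if (length(sel)) {
      ks <- lapply(1:3, function(x) ab[[x]]$k1[sel])
      ks[[a]] <- ab[[a]]$k2[sel]
      req_point <- c(req_point, list(sel))
      req_region <- c(req_region, list(
        .region_index(nmap, ks[[1]], ks[[2]], ks[[3]])))
      req_slot <- c(req_slot, list(rep(a, length(sel))))
    }
  }
  req <- data.frame(point = unlist(req_point), region = unlist(req_region),
                    slot = unlist(req_slot))
  vals <- numeric(nrow(req))
  grads <- if (gradient) matrix(0, nrow(req), 3L)
  for (r in unique(req$region)) {
    rows <- which(req$region == r)
    ev <- .region_eval(nmap, r, coords[req$point[rows], , drop = FALSE],
                       gradient = gradient)
    vals[rows] <- ev$value
    if (gradient) grads[rows, ] <- ev$grad
  }

  # Base-region requests are rows 1..n_pts in point order.
  base_val <- vals[seq_len(n_pts)]
  base_grad <- if (gradient) grads[seq_len(n_pts), , drop = FALSE]
  d_out <- base_val * (n_ov == 0L)
  g_out <- if (gradient) base_grad * (n_ov == 0L)

  for (a in 1:3) {
    rows <- which(req$slot == a)
    if (!length(rows)) next
    pts <- req$point[rows]
    w1 <- ab[[a]]$w1[pts]
    d_out[pts] <- d_out[pts] +
      (w1 * base_val[pts] + (1 - w1) * vals[rows]) / n_ov[pts]
    if (gradient) {
      gg <- (w1 * base_grad[pts, , drop = FALSE] +
               (1 - w1) * grads[rows, , drop = FALSE]) / n_ov[pts]
      gg[, a] <- gg[, a] +
        ab[[a]]$dw1[pts] * (base_val[pts] - vals[rows]) / n_ov[pts]
      g_out[pts, ] <- g_out[pts, ] + gg
    }
  }
  list(d_out = d_out, grad = g_out)
}

.check_bounds <- function(nmap, coords) {
  b <- cbind(nmap$origin,
             nmap$origin + (nmap$shape - 1) * nmap$voxel_size)
  bad <- coords[, 1] < b[1, 1] | coords[, 1] > b[1, 2] |
    coords[, 2] < b[2, 1] | coords[, 2] > b[2, 2] |
    coords[, 3] < b[3, 1] | coords[, 3] > b[3, 2]
  if (any(bad))
    stop("query outside the map's spatial domain (", sum(bad),
         " point(s)); bounds are [",
         paste(apply(signif(b, 4), 1, paste, collapse = ", "),
               collapse = "] x ["), "]")
  invisible(TRUE)
}

#' Query a neural map
#'
#' Evaluates the fitted continuous density field, or its spatial gradient,
#' at arbitrary Angstrom coordinates. A point covered by a single
#' sub-region is answered by that region's network; inside overlap bands
#' the two networks flanking each overlapped axis are blended linearly by
#' the coordinate's position along the overlap, averaged over the
#' overlapped axes. Network outputs are rescaled from the internal
#' `[-1, 1]` range to the nominal `[0, 1]` density scale; values are not
#' clamped, so interpolation may exceed the training range. Gradients are
#' exact derivatives of the blended field (differentiating through the
#' blend weights), in 1/Angstrom.
#'
#' @param object a [neural_map()].
#' @param coords N x 3 matrix (or length-3 vector) of Angstrom coordinates
#'   inside the map; outside points raise an error.
#' @param type `"density"` for a length-N vector, `"gradient"` for an
#'   N x 3 matrix, or `"both"` for a list with both.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.neural_map <- function(object, coords,
                               type = c("density", "gradient", "both"),
                               ...) {
  type <- match.arg(type)
  coords <- matrix(as.numeric(coords), ncol = 3L)
  .check_bounds(object, coords)
  ev <- .nm_eval(object, coords, gradient = type != "density")
  d <- (ev$d_out + 1) / 2
  switch(type,
         density = d,
         gradient = ev$grad / 2,
         both = list(density = d, gradient = ev$grad / 2))
}

#' Resample a neural map onto a regular grid
#'
#' Fills a grid of spacing `voxel_size` anchored at the map origin with
#' densities on the nominal `[0, 1]` scale (or back on the raw input scale
#' with `rescale = "map"`). The grid has `floor(extent / voxel_size) + 1`
#' points per axis.
#'
#' @param nmap a [neural_map()].
#' @param voxel_size output grid spacing in Angstrom.
#' @param rescale `"normalized"` for the `[0, 1]` scale, `"map"` to undo
#'   the first normalization pass back to input map units.
#' @param max_voxels guard against accidentally enormous grids.
#' @return a [voxel_map()].
#' @export
resample <- function(nmap, voxel_size, rescale = c("normalized", "map"),
                     max_voxels = 5e8) {
  stopifnot(inherits(nmap, "neural_map"), voxel_size > 0)
  rescale <- match.arg(rescale)
  extent <- (nmap$shape - 1) * nmap$voxel_size
  dims <- as.integer(floor(extent / voxel_size)) + 1L
  if (prod(dims) > max_voxels)
    stop("resampled grid would hold ", prod(dims),
         " voxels (cap ", max_voxels, ")")
  grid <- as.matrix(expand.grid(
    x = nmap$origin[1] + (seq_len(dims[1]) - 1L) * voxel_size,
    y = nmap$origin[2] + (seq_len(dims[2]) - 1L) * voxel_size,
    z = nmap$origin[3] + (seq_len(dims[3]) - 1L) * voxel_size))
  vals <- numeric(nrow(grid))
  chunk <- 65536L
  for (lo in seq(1L, nrow(grid), by = chunk)) {
    hi <- min(nrow(grid), lo + chunk - 1L)
    vals[lo:hi] <- predict(nmap, grid[lo:hi, , drop = FALSE])
  }
  if (rescale == "map")
    vals <- vals * (nmap$norm$d_max - nmap$norm$d_min) + nmap$norm$d_min
  voxel_map(array(vals, dim = dims), voxel_size = voxel_size,
            origin = nmap$origin, resolution = nmap$resolution)
}

#' Tri-linear interpolation of a voxel map
#'
#' Standard baseline: each query is the weighted sum of its 8 surrounding
#' voxel-centre values. Queries outside the voxel-centre hull raise an
#' error.
#'
#' @param map a [voxel_map()].
#' @param coords N x 3 matrix (or length-3 vector) of Angstrom coordinates.
#' @param values optional replacement array with the same shape as
#'   `map$data` (e.g. normalized densities) to interpolate instead.
#' @return length-N vector of interpolated values.
#' @export
trilinear <- function(map, coords, values = NULL) {
  stopifnot(inherits(map, "voxel_map"))
  arr <- values %||% map$data
  stopifnot(identical(dim(arr), dim(map$data)))
  coords <- matrix(as.numeric(coords), ncol = 3L)
  tt <- coord_to_index(map, coords)
  eps <- 1e-9
  for (a in 1:3) {
    bad <- tt[, a] < -eps | tt[, a] > map$shape[a] - 1 + eps
    if (any(bad))
      stop("tri-linear query outside the voxel-centre hull (", sum(bad),
           " point(s) on axis ", a, ")")
  }
  i0 <- pmin(pmax(floor(tt), 0), rep(map$shape - 2L, each = nrow(tt)))
  i0 <- matrix(as.integer(i0), ncol = 3L)
  f <- tt - i0
  f <- pmin(pmax(f, 0), 1)
  v <- numeric(nrow(coords))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
      (if (dj) f[, 2] else 1 - f[, 2]) *
      (if (dk) f[, 3] else 1 - f[, 3])
    v <- v + w * arr[cbind(i0[, 1] + di + 1L, i0[, 2] + dj + 1L,
                           i0[, 3] + dk + 1L)]
  }
  v
}
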