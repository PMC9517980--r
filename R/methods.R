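# S3 methods for fitted neural maps.

#' @export
print.neural_map <- function(x, ...) {
  cat("Neural cryo-EM map\n")
  cat("  grid       :", paste(x$shape, collapse = " x "), "voxels,",
      length(x$regions), "region(s)\n")
  cat("  voxel size :", paste(signif(x$voxel_size, 4), collapse = ", "),
      "Angstrom\n")
  lmins <- vapply(x$regions, `[[`, numeric(1), "l_min")
  cat("  fit        : l_min", paste(signif(range(lmins), 3),
                                    collapse = " .. "), "\n")
  if (!is.null(x$resolution))
    cat("  resolution :", x$resolution, "Angstrom\n")
  invisible(x)
}

#' Summarize a fitted neural map
#'
#' @param object a [neural_map()].
#' @param ... unused.
#' @return a `summary.neural_map` with a per-region table of voxel counts,
#'   epochs, best losses and exit reasons.
#' @export
summary.neural_map <- function(object, ...) {
  tab <- do.call(rbind, lapply(seq_along(object$regions), function(r) {
    reg <- object$regions[[r]]
    data.frame(region = r,
               voxels = prod(reg$range[, "end"] - reg$range[, "start"]),
               epochs = reg$epochs, l_min = reg$l_min,
               exit = reg$exit_reason)
  }))
  structure(list(regions = tab, shape = object$shape,
                 norm = object$norm, resolution = object$resolution),
            class = "summary.neural_map")
}

#' @export
print.summary.neural_map <- function(x, ...) {
  cat("Neural cryo-EM map:", paste(x$shape, collapse = " x "),
      "voxels\n")
  cat(sprintf("Normalization: d_max %.4g, mean(d1) %.4g, sd(d1) %.4g\n",
              x$norm$d_max, x$norm$mean_d1, x$norm$sd_d1))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Fitted densities at the training voxel centres
#'
#' @param object a [neural_map()].
#' @param ... unused.
#' @return array of fitted densities on the `[0, 1]` scale, same shape as
#'   the training map.
#' @export
fitted.neural_map <- function(object, ...) {
  dims <- object$shape
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  coords <- sweep(sweep(idx, 2L, object$voxel_size, `*`), 2L,
                  object$origin, `+`)
  vals <- numeric(nrow(coords))
  chunk <- 65536L
  for (lo in seq(1L, nrow(coords), by = chunk)) {
    hi <- min(nrow(coords), lo + chunk - 1L)
    vals[lo:hi] <- predict(object, coords[lo:hi, , drop = FALSE])
  }
  array(vals, dim = dims)
}

#' Training residuals of a neural map
#'
#' Difference between the fitted field and the normalized training
#' densities at the voxel centres, on the `[0, 1]` scale.
#'
#' @param object a [neural_map()].
#' @param map the training [voxel_map()] (its normalized values are
#'   recomputed; must match the stored geometry).
#' @param ... unused.
#' @return array of residuals (fitted minus training), same shape as the
#'   map.
#' @export
residuals.neural_map <- function(object, map, ...) {
  stopifnot(inherits(map, "voxel_map"),
            identical(as.integer(map$shape), as.integer(object$shape)))
  fitted.neural_map(object) - normalize_density(map)$d1
}

#' Plot training losses of a neural map
#'
#' Draws each region's epoch-loss trace on a log scale with the exit-band
#' bounds.
#'
#' @param x a [neural_map()] (freshly fitted; loss traces are not
#'   persisted to disk).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.neural_map <- function(x, ...) {
  traces <- lapply(x$regions, `[[`, "losses")
  if (any(vapply(traces, is.null, logical(1))))
    stop("loss traces are unavailable (map was loaded from disk)")
  n <- max(vapply(traces, length, integer(1)))
  m <- sapply(traces, function(tr) c(tr, rep(NA, n - length(tr))))
  graphics::matplot(m, type = "l", log = "y", xlab = "epoch",
                    ylab = "MSE loss", ...)
  graphics::abline(h = c(x$control$hard_stop, x$control$plateau_hi),
                   lty = 3)
  invisible(x)
}

#' Plot a density graph projection
#'
#' 2-D projection of nodes (sized by density) and edges.
#'
#' @param x a `density_graph`.
#' @param axes which two coordinate axes to project onto.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_graph <- function(x, axes = c(1, 2), ...) {
  cols <- c("x", "y", "z")[axes]
  nd <- x$nodes
  graphics::plot(nd[[cols[1]]], nd[[cols[2]]], pch = 19,
                 cex = 0.5 + nd$density, xlab = paste(cols[1], "(Angstrom)"),
                 ylab = paste(cols[2], "(Angstrom)"), asp = 1, ...)
  if (nrow(x$edges))
    graphics::segments(nd[[cols[1]]][x$edges$from],
                       nd[[cols[2]]][x$edges$from],
                       nd[[cols[1]]][x$edges$to],
                       nd[[cols[2]]][x$edges$to], col = "grey50")
  invisible(x)
}
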