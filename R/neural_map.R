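# Fitting sinusoidal networks to map sub-regions and assembling them into a
# queryable neural map.

#' Sinusoidal network architecture
#'
#' The per-region network is a fully connected multi-layer perceptron with a
#' sinusoidal input layer, `hidden_layers` hidden sinusoidal layers of
#' `hidden_features` units, and a final linear output layer. Sine layers
#' compute `sin(omega0 * (W x + b))`. Weights are drawn from
#' `U(-sqrt(6/n), sqrt(6/n))` for the first layer and
#' `U(-(1/omega0) * sqrt(6/n), (1/omega0) * sqrt(6/n))` for all subsequent
#' layers, with `n = hidden_features`.
#'
#' @param hidden_layers number of hidden sinusoidal layers.
#' @param hidden_features units per hidden layer.
#' @param omega0 frequency scale of the sine layers.
#' @return a `siren_config` list.
#' @export
siren_config <- function(hidden_layers = 4L, hidden_features = 256L,
                         omega0 = 30) {
  stopifnot(hidden_layers >= 1L, hidden_features >= 1L, omega0 > 0)
  structure(list(in_dim = 3L, hidden_layers = as.integer(hidden_layers),
                 hidden_features = as.integer(hidden_features),
                 out_dim = 1L, omega0 = omega0),
            class = "siren_config")
}

#' Training settings
#'
#' Training minimizes the mean squared error with Adam and runs to the
#' "natural fit point": the loop exits immediately once the best observed
#' loss `l_min` drops below `hard_stop`, or after `patience` epochs without
#' improvement while `hard_stop <= l_min < plateau_hi`. There are no
#' validation splits; the network is meant to fit every voxel of its
#' region. A safety cap bounds the epoch count; reaching it raises a
#' warning rather than failing.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param hard_stop loss below which training exits immediately.
#' @param plateau_hi upper edge of the plateau exit band.
#' @param patience epochs without improvement tolerated inside the band.
#' @param max_epochs safety cap on epochs.
#' @param batch_size full-batch epochs are used up to this many voxels;
#'   larger regions train in shuffled mini-batches of this size, one pass
#'   over all voxels counting as one epoch.
#' @return a `train_control` list.
#' @export
train_control <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                          adam_eps = 1e-8, hard_stop = 1e-5,
                          plateau_hi = 4e-4, patience = 25L,
                          max_epochs = 20000L, batch_size = 32768L) {
  stopifnot(lr > 0, hard_stop > 0, plateau_hi > hard_stop, patience >= 1L)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 hard_stop = hard_stop, plateau_hi = plateau_hi,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size)),
            class = "train_control")
}

#' Initialize network weights
#'
#' @param config a [siren_config()].
#' @param seed integer seed; identical seeds give identical weights.
#' @return list with components `W` (list of weight matrices, output rows x
#'   input columns) and `b` (list of bias vectors).
#' @export
init_siren <- function(config, seed = 1) {
  stopifnot(inherits(config, "siren_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  n <- config$hidden_features
  first_bound <- sqrt(6 / n)
  later_bound <- sqrt(6 / n) / config$omega0
  dims <- rbind(c(n, config$in_dim),
                matrix(n, nrow = config$hidden_layers, ncol = 2L),
                c(config$out_dim, n))
  W <- vector("list", nrow(dims))
  b <- vector("list", nrow(dims))
  for (l in seq_len(nrow(dims))) {
    bound <- if (l == 1L) first_bound else later_bound
    W[[l]] <- matrix(stats::runif(prod(dims[l, ]), -bound, bound),
                     nrow = dims[l, 1L], ncol = dims[l, 2L])
    b[[l]] <- stats::runif(dims[l, 1L], -bound, bound)
  }
  list(W = W, b = b)
}

#' Train one network on a region's voxels
#'
#' @param coords N x 3 matrix of local coordinates in `[-1, 1]^3`.
#' @param target length-N vector of training densities on the `[-1, 1]`
#'   scale.
#' @param config a [siren_config()].
#' @param control a [train_control()].
#' @param seed seed for weight initialization (and mini-batch shuffling).
#' @param mock_losses if supplied, the optimizer is bypassed and the exit
#'   rule is driven by this loss sequence (testing hook for the exit
#'   criterion; weights are returned untouched).
#' @return list with `weights` (best observed), `losses`, `l_min`,
#'   `best_epoch`, `epochs`, `exit_reason` (one of `"hard_stop"`,
#'   `"plateau"`, `"max_epochs"`).
#' @export
train_siren <- function(coords, target, config = siren_config(),
                        control = train_control(), seed = 1,
                        mock_losses = NULL) {
  stopifnot(inherits(config, "siren_config"),
            inherits(control, "train_control"))
  if (is.null(mock_losses)) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 1L || nrow(coords) != length(target))
      stop("need at least one voxel and matching target length")
  } else {
    coords <- matrix(0, 1L, 3L)
    target <- 0
  }
  w0 <- init_siren(config, seed = seed)
  fit <- cpp_siren_train(w0, t(coords), as.numeric(target),
                         config$omega0, control$lr, control$beta1,
                         control$beta2, control$adam_eps,
                         control$hard_stop, control$plateau_hi,
                         control$patience, control$max_epochs,
                         control$batch_size,
                         shuffle_seed = seed %% .Machine$integer.max,
                         mock_losses = as.numeric(mock_losses %||% numeric()))
  if (fit$exit_reason == "max_epochs" && is.null(mock_losses))
    warning("epoch safety cap reached (l_min = ", signif(fit$l_min, 4),
            "); returning best weights so far")
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a neural representation of a density map
#'
#' Normalizes the map, tiles the voxel grid into overlapping sub-regions of
#' at most 64 voxels per axis, and trains one sinusoidal network per region
#' on the voxel-centre coordinates (scaled per region to `[-1, 1]^3`)
#' against the `[-1, 1]`-normalized densities. The returned object answers
#' continuous density and gradient queries at any Angstrom coordinate
#' inside the map through [predict.neural_map()].
#'
#' @param map a [voxel_map()].
#' @param resolution reported map resolution in Angstrom (defaults to the
#'   map's `resolution` field, if any); stored for graph extraction.
#' @param config a [siren_config()].
#' @param control a [train_control()].
#' @param seed base seed; region `r` trains with seed `seed + r - 1`, so
#'   results are independent of training order.
#' @param verbose print per-region training summaries.
#' @return an object of class `neural_map`.
#' @export
neural_map <- function(map, resolution = NULL, config = siren_config(),
                       control = train_control(), seed = 1,
                       verbose = FALSE) {
  stopifnot(inherits(map, "voxel_map"))
  resolution <- resolution %||% map$resolution
  norm <- normalize_density(map)
  plan <- plan_tiling(map$shape)
  regions <- vector("list", length(plan$regions))
  for (r in seq_along(plan$regions)) {
    reg <- plan$regions[[r]]
    bounds <- region_bounds(reg, map$origin, map$voxel_size)
    ii <- (reg[1L, "start"]:(reg[1L, "end"] - 1L))
    jj <- (reg[2L, "start"]:(reg[2L, "end"] - 1L))
    kk <- (reg[3L, "start"]:(reg[3L, "end"] - 1L))
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    coords <- index_to_coord(map, idx)
    local <- region_local_coords(coords, bounds)
    target <- norm$d_train[idx + 1L]
    fit <- tryCatch(
      train_siren(local, target, config = config, control = control,
                  seed = seed + r - 1L),
      error = function(e) stop("training failed in region ", r, ": ",
                               conditionMessage(e)))
    if (verbose)
      message(sprintf("region %d/%d: %d voxels, %d epochs, l_min %.3g (%s)",
                      r, length(plan$regions), nrow(idx), fit$epochs,
                      fit$l_min, fit$exit_reason))
    regions[[r]] <- list(range = reg, bounds = bounds,
                         weights = fit$weights, l_min = fit$l_min,
                         epochs = fit$epochs, exit_reason = fit$exit_reason,
                         losses = fit$losses, seed = seed + r - 1L)
  }
  structure(list(regions = regions, plan = plan, norm = norm$record,
                 origin = map$origin, voxel_size = map$voxel_size,
                 shape = map$shape, resolution = resolution,
                 config = config, control = control, seed = seed),
            class = "neural_map")
}

# ---- persistence -----------------------------------------------------------

#' Save / load a neural map
#'
#' The on-disk format is a directory holding `meta.json` (tiling plan,
#' normalization record, geometry, architecture, training settings, seeds,
#' per-region training diagnostics) and one `region_<i>_<j>_<k>.rds` weight
#' file per sub-region.
#'
#' @param nmap a [neural_map()].
#' @param path directory to create or read.
#' @return `save_neural_map` returns `path` invisibly; `load_neural_map`
#'   returns the restored `neural_map`.
#' @export
save_neural_map <- function(nmap, path) {
  stopifnot(inherits(nmap, "neural_map"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  region_files <- character(length(nmap$regions))
  meta_regions <- vector("list", length(nmap$regions))
  for (r in seq_along(nmap$regions)) {
    reg <- nmap$regions[[r]]
    ai <- attr(reg$range, "axis_index")
    region_files[r] <- sprintf("region_%d_%d_%d.rds", ai[1], ai[2], ai[3])
    saveRDS(reg$weights, file.path(path, region_files[r]))
    meta_regions[[r]] <- list(file = region_files[r], axis_index = ai,
                              start = unname(reg$range[, "start"]),
                              end = unname(reg$range[, "end"]),
                              l_min = reg$l_min, epochs = reg$epochs,
                              exit_reason = reg$exit_reason,
                              seed = reg$seed)
  }
  meta <- list(format = "neural-map/1",
               shape = nmap$shape, origin = nmap$origin,
               voxel_size = nmap$voxel_size,
               resolution = nmap$resolution,
               norm = unclass(nmap$norm),
               config = unclass(nmap$config),
               control = unclass(nmap$control),
               seed = nmap$seed, regions = meta_regions)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_neural_map
#' @export
load_neural_map <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a neural map directory (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "neural-map/1"))
    stop("unsupported neural map format: ", meta$format %||% "<missing>")
  plan <- plan_tiling(meta$shape)
  if (length(plan$regions) != nrow(meta$regions))
    stop("metadata region count (", nrow(meta$regions),
         ") does not match tiling of shape ",
         paste(meta$shape, collapse = "x"))
  config <- do.call(siren_config,
                    meta$config[c("hidden_layers", "hidden_features",
                                  "omega0")])
  control <- do.call(train_control, meta$control)
  regions <- vector("list", length(plan$regions))
  for (r in seq_along(plan$regions)) {
    mr <- meta$regions[r, ]
    wf <- file.path(path, mr$file)
    if (!file.exists(wf)) stop("missing region weights file: ", wf)
    reg <- plan$regions[[r]]
    if (!all(reg[, "start"] == mr$start[[1]]) ||
        !all(reg[, "end"] == mr$end[[1]]))
      stop("region ", r, " geometry mismatch between metadata and tiling")
    regions[[r]] <- list(range = reg,
                         bounds = region_bounds(reg, meta$origin,
                                                meta$voxel_size),
                         weights = readRDS(wf), l_min = mr$l_min,
                         epochs = mr$epochs, exit_reason = mr$exit_reason,
                         losses = NULL, seed = mr$seed)
  }
  norm <- structure(as.list(meta$norm), class = "norm_record")
  structure(list(regions = regions, plan = plan, norm = norm,
                 origin = meta$origin, voxel_size = meta$voxel_size,
                 shape = meta$shape, resolution = meta$resolution,
                 config = config, control = control, seed = meta$seed),
            class = "neural_map")
}
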