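#' Simulate multi-volume raster acquisition of a phantom
#'
#' Each A-scan samples the phantom at its nominal transverse position minus
#' the eye displacement evaluated at that A-scan's acquisition time
#' (trilinear interpolation), so features appear shifted by the
#' displacement in the recorded volume. Multiplicative illumination bias
#' and multiplicative speckle (gamma-distributed, unit mean) plus additive
#' detector noise are applied after sampling. A-scans whose displaced
#' position falls outside the phantom are filled with background and
#' flagged.
#'
#' @param phantom a [make_phantom()] result.
#' @param protocol an [acquisition_protocol()]; its field of view must lie
#'   within the phantom.
#' @param traces list of [simulate_motion()] traces, one per volume, each
#'   covering `[0, vol_duration_s]` (volume-local time), or `NULL` for no
#'   motion.
#' @param bias optional simulated illumination bias: a list (one element
#'   per volume) of `n_fast x n_bscans` multiplicative gain matrices, as
#'   produced by [make_bias()]; `NULL` for none.
#' @param speckle_contrast contrast (sd/mean) of the multiplicative
#'   speckle; 0 disables.
#' @param detector_sd sd of the additive detector noise; 0 disables.
#' @param seed random seed for the noise.
#' @param origin_um scan-region origin within the phantom (x, y um); lets
#'   two visits image the same retina at a fixation offset. Recorded
#'   coordinates stay scan-relative.
#' @return a list of `raster_volume` objects.
#' @export
acquire <- function(phantom, protocol, traces = NULL, bias = NULL,
                    speckle_contrast = 0.35, detector_sd = 0.01, seed = 1L,
                    origin_um = c(0, 0)) {
  stopifnot(inherits(phantom, "phantom"), inherits(protocol, "acquisition_protocol"))
  if (!is.null(traces)) stopifnot(length(traces) == protocol$n_volumes)
  if (!is.null(bias)) stopifnot(length(bias) == protocol$n_volumes)
  cfg <- phantom$cfg
  set.seed(seed)
  lapply(seq_len(protocol$n_volumes), function(v) {
    dir <- protocol$directions[v]
    tmat <- ascan_times(protocol, v)  # n_fast x n_bscans, absolute time
    tloc <- tmat - volume_start(protocol, v)
    if (!is.null(traces)) {
      d <- eval_trace(traces[[v]], as.numeric(tloc))
    } else {
      d <- matrix(0, length(tloc), 3)
    }
    # nominal transverse positions (um) of every A-scan, acquisition order
    fast_um <- (seq_len(protocol$n_fast) - 1) * protocol$spacing_um
    slow_um <- (seq_len(protocol$n_bscans) - 1) * protocol$spacing_um
    if (dir == "x") {
      x_um <- rep(fast_um, times = protocol$n_bscans)
      y_um <- rep(slow_um, each = protocol$n_fast)
    } else {
      y_um <- rep(fast_um, times = protocol$n_bscans)
      x_um <- rep(slow_um, each = protocol$n_fast)
    }
    sm <- sample_columns_cpp(phantom$grid,
                             (x_um + origin_um[1] - d[, 1]) / cfg$dxy_um,
                             (y_um + origin_um[2] - d[, 2]) / cfg$dxy_um,
                             -d[, 3] / cfg$dz_um,
                             cfg$background)
    grid <- sm$intensity
    if (!is.null(bias)) grid <- grid * rep(as.numeric(bias[[v]]), each = nrow(grid))
    if (speckle_contrast > 0) {
      sh <- 1 / speckle_contrast^2
      grid <- grid * rgamma(length(grid), shape = sh, rate = sh)
    }
    if (detector_sd > 0) grid <- pmax(0, grid + rnorm(length(grid), 0, detector_sd))
    dim(grid) <- c(cfg$nz, protocol$n_fast, protocol$n_bscans)
    new_raster_volume(grid, protocol, dir, v, times = tmat,
                      oob = matrix(sm$oob, protocol$n_fast, protocol$n_bscans),
                      meta = list(seed = seed,
                                  trace = if (!is.null(traces)) traces[[v]] else NULL,
                                  bias = if (!is.null(bias)) bias[[v]] else NULL,
                                  speckle_contrast = speckle_contrast,
                                  detector_sd = detector_sd,
                                  phantom_dxy_um = cfg$dxy_um,
                                  phantom_dz_um = cfg$dz_um))
  })
}

#' Construct a raster volume container
#'
#' @param grid `nz x n_fast x n_bscans` non-negative intensity array;
#'   `grid[, i, j]` is A-scan i of B-scan j.
#' @param protocol the [acquisition_protocol()] it was acquired under.
#' @param direction fast-axis direction, `"x"` or `"y"`.
#' @param index 1-based volume index within the acquisition.
#' @param times per-A-scan acquisition time matrix (`n_fast x n_bscans`, s);
#'   recomputed from the protocol when `NULL`.
#' @param oob logical matrix flagging A-scans sampled outside the phantom.
#' @param meta free-form metadata list.
#' @return a `raster_volume`.
#' @export
new_raster_volume <- function(grid, protocol, direction, index = 1L,
                              times = NULL, oob = NULL, meta = list()) {
  d <- dim(grid)
  if (length(d) != 3 || d[2] != protocol$n_fast || d[3] != protocol$n_bscans)
    stopf("grid dimensions (%s) do not match protocol (nz x %d x %d)",
          paste(d, collapse = " x "), protocol$n_fast, protocol$n_bscans)
  if (is.null(times)) times <- ascan_times(protocol, index)
  structure(list(grid = grid, protocol = protocol, direction = direction,
                 index = as.integer(index), times = times,
                 mask = rep(TRUE, protocol$n_bscans),
                 oob = oob, meta = meta),
            class = "raster_volume")
}

#' @export
print.raster_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<raster_volume #%d> %s-fast, %d x %d A-scans x %d depth, %d/%d B-scans valid\n",
              x$index, x$direction, d[2], d[3], d[1], sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Smooth synthetic illumination bias fields
#'
#' Generates, per volume, a multiplicative gain that varies smoothly along
#' the fast axis and slowly across B-scans, emulating illumination changes
#' during acquisition.
#'
#' @param protocol an [acquisition_protocol()].
#' @param amplitude relative amplitude (e.g. 0.2 for about +/-20 percent).
#' @param n_ctrl control points along the fast axis.
#' @param seed random seed.
#' @return list of `n_fast x n_bscans` gain matrices, one per volume.
#' @export
make_bias <- function(protocol, amplitude = 0.2, n_ctrl = 5L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(protocol$n_volumes), function(v) {
    ctrl <- matrix(rnorm(n_ctrl * 3), n_ctrl, 3)
    ctrl <- ctrl / max(abs(ctrl), 1e-9) * amplitude
    fast <- seq(0, 1, length.out = protocol$n_fast)
    slow <- seq(0, 1, length.out = protocol$n_bscans)
    curves <- vapply(1:3, function(k)
      splinefun(seq(0, 1, length.out = n_ctrl), ctrl[, k])(fast),
      numeric(protocol$n_fast))
    wslow <- cbind((1 - slow)^2, 2 * slow * (1 - slow), slow^2)
    g <- 1 + curves %*% t(wslow)
    matrix(pmax(g, 0.2), nrow(g), ncol(g))
  })
}

#' Inject blink artifacts into a volume
#'
#' Sets the listed B-scan ranges to the detector noise floor and records
#' the injected ground truth in the volume metadata. Overlapping ranges
#' are merged.
#'
#' @param volume a `raster_volume`.
#' @param intervals list of integer vectors (1-based B-scan index ranges),
#'   or a single integer vector.
#' @param floor intensity floor the blinked B-scans are set to.
#' @return the modified `raster_volume`.
#' @export
inject_blinks <- function(volume, intervals, floor = 0.002) {
  stopifnot(inherits(volume, "raster_volume"))
  if (!is.list(intervals)) intervals <- list(intervals)
  idx <- sort(unique(unlist(intervals)))
  if (!length(idx)) return(volume)
  if (any(idx < 1 | idx > dim(volume$grid)[3]))
    stopf("blink interval outside B-scan range 1..%d", dim(volume$grid)[3])
  volume$grid[, , idx] <- floor
  volume$meta$blinks_gt <- idx
  volume$meta$blink_floor <- floor
  volume
}
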