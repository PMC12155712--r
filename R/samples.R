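# axial voxel spacing of a volume (um); recorded at acquisition/read time
vol_dz <- function(volume) volume$meta$phantom_dz_um %||% 2

# nominal transverse positions (um) of every A-scan in acquisition order
nominal_positions <- function(volume) {
  p <- volume$protocol
  fast_um <- (seq_len(p$n_fast) - 1) * p$spacing_um
  slow_um <- (seq_len(p$n_bscans) - 1) * p$spacing_um
  if (volume$direction == "x") {
    list(x = rep(fast_um, times = p$n_bscans),
         y = rep(slow_um, each = p$n_fast))
  } else {
    list(x = rep(slow_um, each = p$n_fast),
         y = rep(fast_um, times = p$n_bscans))
  }
}

#' Motion-correct the A-scan positions of a volume
#'
#' Shifts every unmasked A-scan's nominal 3D position by minus the
#' displacement evaluated at its acquisition time. Intensities are left
#' untouched: the correction is purely geometric. Masked (blink) B-scans
#' are dropped and never contribute downstream.
#'
#' @param volume a `raster_volume`.
#' @param model a `displacement_model` from [estimate_motion()], a
#'   `motion_trace` (ground truth, volume-local time), or `NULL` for zero
#'   correction.
#' @return a `corrected_samples` object: `intensity` (nz x nA matrix, one
#'   column per kept A-scan in acquisition order), corrected `x_um`,
#'   `y_um`, per-A-scan axial offset `z_off_um` (tissue depth of voxel k is
#'   `k * dz_um + z_off_um`), `bscan` source indices, and geometry fields.
#' @export
correct_volume <- function(volume, model = NULL) {
  stopifnot(inherits(volume, "raster_volume"))
  p <- volume$protocol
  keep <- which(volume$mask)
  pos <- nominal_positions(volume)
  tmat <- volume$times
  sel <- as.vector(outer(seq_len(p$n_fast), (keep - 1) * p$n_fast, `+`))
  tt <- as.numeric(tmat)[sel]
  if (is.null(model)) {
    d <- matrix(0, length(tt), 3)
  } else if (inherits(model, "motion_trace")) {
    d <- eval_trace(model, tt - volume_start(p, volume$index))
  } else if (inherits(model, "displacement_model")) {
    d <- eval_displacement(model, volume$index, tt)
  } else stopf("model must be NULL, a motion_trace or a displacement_model")
  grid <- volume$grid
  dim(grid) <- c(dim(grid)[1], p$n_fast * p$n_bscans)
  structure(list(
    intensity = grid[, sel, drop = FALSE],
    x_um = pos$x[sel] - d[, 1],
    y_um = pos$y[sel] - d[, 2],
    z_off_um = -d[, 3],
    bscan = rep(keep, each = p$n_fast),
    volume = volume$index, direction = volume$direction,
    dz_um = vol_dz(volume), pitch_um = p$spacing_um,
    protocol = p
  ), class = "corrected_samples")
}

#' @export
print.corrected_samples <- function(x, ...) {
  cat(sprintf("<corrected_samples> volume %d (%s-fast): %d A-scans x %d depth\n",
              x$volume, x$direction, ncol(x$intensity), nrow(x$intensity)))
  invisible(x)
}

# Scatter corrected samples into a common (nz, nx, ny) grid.
# extra_zshift_um: per-A-scan additional axial shift (e.g. flattening), or 0.
# Returns list(sum, wsum) accumulation arrays (per volume if per_volume).
scatter_samples <- function(samples_list, nz, nx, ny, dz_um, pitch_um,
                            extra_zshift_um = NULL, per_volume = FALSE,
                            transform = identity) {
  mk <- function() {
    a <- numeric(nz * nx * ny); dim(a) <- c(nz, nx, ny); a
  }
  res <- list()
  tot_sum <- mk(); tot_w <- mk()
  for (i in seq_along(samples_list)) {
    s <- samples_list[[i]]
    ez <- if (is.null(extra_zshift_um)) 0 else extra_zshift_um[[i]]
    zs <- (s$z_off_um + ez) / dz_um
    if (length(zs) == 1L) zs <- rep(zs, ncol(s$intensity))
    cols <- transform(s$intensity)
    if (per_volume) {
      sv <- mk(); wv <- mk()
      scatter_cpp(cols, s$x_um / pitch_um, s$y_um / pitch_um, zs, sv, wv)
      res[[i]] <- list(sum = sv, wsum = wv)
      tot_sum <- tot_sum + sv; tot_w <- tot_w + wv
    } else {
      scatter_cpp(cols, s$x_um / pitch_um, s$y_um / pitch_um, zs, tot_sum, tot_w)
    }
  }
  list(sum = tot_sum, wsum = tot_w, per_volume = res)
}

# value grid with NaN holes from accumulators
value_grid <- function(sum, wsum, wmin = 0.25) {
  v <- sum / wsum
  v[wsum < wmin] <- NA_real_
  dim(v) <- dim(sum)
  v
}
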