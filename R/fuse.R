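#' Segment Bruch's membrane (or the posterior RPE edge) per B-scan
#'
#' Deterministic dynamic-programming surface finding. For BrM, each
#' B-scan's cost image rewards bright voxels and penalizes bright signal
#' posterior to the candidate depth, so the minimum-cost continuous path
#' (slope-limited, one depth per A-scan) follows the posterior-most bright
#' band -- BrM stays put underneath drusen, whose material and elevated
#' RPE lie anterior to it. The posterior RPE edge (pRPE) is then located
#' per A-scan as the strongest negative axial gradient between the RPE
#' brightness peak and BrM.
#'
#' @param volume a `raster_volume` or `fused_volume`.
#' @param layer `"brm"` or `"prpe"`.
#' @param max_slope_vox slope limit of the DP path (axial voxels per
#'   A-scan).
#' @param below_thresh reflectivity above which posterior signal is
#'   penalized (relative to the B-scan's robust maximum).
#' @param smooth_sigma_px transverse Gaussian smoothing applied to each
#'   B-scan before segmentation.
#' @return an `oct_surface`: `depth_um` matrix (fast x slow for raster
#'   volumes, x by y for fused volumes), `valid` mask, `layer` tag and
#'   grid info.
#' @export
segment_surface <- function(volume, layer = c("brm", "prpe"),
                            max_slope_vox = 2L, below_thresh = 0.35,
                            smooth_sigma_px = 1.5) {
  layer <- match.arg(layer)
  fused <- inherits(volume, "fused_volume")
  grid <- if (fused) volume$intensity else volume$grid
  dzu <- if (fused) volume$dz_um else vol_dz(volume)
  d <- dim(grid)
  nb <- d[3]
  depth <- matrix(NA_real_, d[2], nb)
  valid <- matrix(FALSE, d[2], nb)
  mask <- if (fused) rep(TRUE, nb) else volume$mask
  for (j in seq_len(nb)) {
    if (!mask[j]) next
    im <- grid[, , j]
    im[!is.finite(im)] <- 0
    if (smooth_sigma_px > 0)
      im <- EBImage::imageData(EBImage::gblur(im, sigma = smooth_sigma_px))
    mx <- quantile(im, 0.999, names = FALSE)
    if (mx <= 0) next
    imn <- pmin(im / mx, 1.5)
    # per-column relative threshold: reflectivity texture scales all bands
    # of a column together, so band/peak ratios are stable under it
    colmax <- apply(imn, 2, quantile, probs = 0.995, names = FALSE)
    excess <- pmax(sweep(imn, 2, below_thresh * pmax(colmax, 0.05), `-`), 0)
    # penalize bright signal strictly deeper than the candidate (with a
    # guard gap so a band's own posterior tail does not penalize its centre)
    gap <- max(1L, round(8 / dzu))
    bright_below <- apply(excess, 2, function(col) {
      cum <- rev(cumsum(rev(col)))
      c(cum[-seq_len(gap)], rep(0, gap))
    })
    cost <- -imn + bright_below
    path <- dp_surface_cpp(cost, as.integer(max_slope_vox))
    zb <- refine_band_center(im, path)
    if (layer == "prpe") {
      zb <- prpe_from_brm(im, zb, dzu)
      zb <- run_med(zb, 5L)
    }
    depth[, j] <- zb * dzu
    valid[, j] <- TRUE
  }
  structure(list(depth_um = depth, valid = valid, layer = layer,
                 dz_um = dzu, fused = fused,
                 direction = if (fused) NA_character_ else volume$direction,
                 volume = if (fused) NA_integer_ else volume$index,
                 protocol = if (fused) NULL else volume$protocol,
                 pitch_um = if (fused) volume$pitch_um else volume$protocol$spacing_um),
            class = "oct_surface")
}

# sub-voxel band centre: intensity-weighted centroid within +/-3 voxels
refine_band_center <- function(im, path) {
  nz <- nrow(im)
  vapply(seq_along(path), function(i) {
    z0 <- path[i] + 1
    win <- max(1, z0 - 3):min(nz, z0 + 3)
    w <- pmax(im[win, i], 0)
    if (sum(w) <= 0) return(as.numeric(path[i]))
    sum((win - 1) * w) / sum(w)
  }, numeric(1))
}

# posterior RPE edge: strongest negative gradient between the RPE peak
# (brightest voxel in a window anterior to BrM) and BrM
prpe_from_brm <- function(im, brm_vox, dzu) {
  nz <- nrow(im)
  win_lo <- pmax(1, round(brm_vox - 120 / dzu))
  win_hi <- pmax(1, round(brm_vox - 6 / dzu))
  vapply(seq_len(ncol(im)), function(i) {
    lo <- win_lo[i]; hi <- min(win_hi[i], nz - 1)
    if (hi <= lo + 2) return(brm_vox[i] - 8 / dzu)
    seg <- im[lo:hi, i]
    zp <- lo + which.max(seg) - 1
    hi2 <- min(round(brm_vox[i] - 2 / dzu), nz - 1)
    if (hi2 <= zp) return(as.numeric(zp))
    g <- diff(im[zp:(hi2 + 1), i])
    zp + which.min(g) - 1
  }, numeric(1))
}

#' @export
print.oct_surface <- function(x, ...) {
  cat(sprintf("<oct_surface> %s, %d x %d positions, depth %.1f-%.1f um, %.1f%% valid\n",
              toupper(x$layer), nrow(x$depth_um), ncol(x$depth_um),
              min(x$depth_um, na.rm = TRUE), max(x$depth_um, na.rm = TRUE),
              100 * mean(x$valid)))
  invisible(x)
}

#' Motion-correct and average per-volume surfaces
#'
#' Applies the estimated displacements to each volume's surface locations
#' (transverse shift of the A-scan position, axial shift of the depth),
#' grids them onto the common transverse raster, and averages the valid
#' displacement-corrected depths per position. Positions with no valid
#' contribution are masked.
#'
#' @param surfaces list of `oct_surface`s, one per volume (raster frame).
#' @param model a `displacement_model`, or `NULL` for zero motion.
#' @return an `oct_surface` in the common frame (x by y).
#' @export
mean_surface <- function(surfaces, model = NULL) {
  stopifnot(length(surfaces) >= 1)
  p <- surfaces[[1]]$protocol
  pitch <- p$spacing_um
  n <- p$n_fast
  sum2 <- matrix(0, n, p$n_bscans); w2 <- matrix(0, n, p$n_bscans)
  for (s in surfaces) {
    pp <- s$protocol
    fast_um <- (seq_len(pp$n_fast) - 1) * pitch
    slow_um <- (seq_len(pp$n_bscans) - 1) * pitch
    for (j in seq_len(pp$n_bscans)) {
      if (!any(s$valid[, j])) next
      m <- if (is.null(model)) c(0, 0, 0) else {
        tj <- volume_start(pp, s$volume) + (j - 0.5) * pp$bscan_period_s
        as.numeric(eval_displacement(model, s$volume, tj))
      }
      if (s$direction == "x") {
        xv <- (fast_um - m[1]) / pitch; yv <- rep((slow_um[j] - m[2]) / pitch, pp$n_fast)
      } else {
        yv <- (fast_um - m[2]) / pitch; xv <- rep((slow_um[j] - m[1]) / pitch, pp$n_fast)
      }
      dep <- s$depth_um[, j] - m[3]
      ok <- s$valid[, j] & is.finite(dep)
      if (!any(ok)) next
      acc <- bilinear_scatter2d(xv[ok], yv[ok], dep[ok], n, p$n_bscans)
      sum2 <- sum2 + acc$sum; w2 <- w2 + acc$w
    }
  }
  depth <- sum2 / w2
  valid <- w2 > 0.25
  depth[!valid] <- NA_real_
  structure(list(depth_um = depth, valid = valid,
                 layer = surfaces[[1]]$layer, dz_um = surfaces[[1]]$dz_um,
                 fused = TRUE, direction = NA_character_,
                 volume = NA_integer_, protocol = p, pitch_um = pitch),
            class = "oct_surface")
}

bilinear_scatter2d <- function(xv, yv, val, nx, ny) {
  s <- matrix(0, nx, ny); w <- matrix(0, nx, ny)
  x0 <- floor(xv); y0 <- floor(yv)
  fx <- xv - x0; fy <- yv - y0
  for (c in 1:4) {
    xi <- x0 + (c == 2 | c == 4)
    yi <- y0 + (c == 3 | c == 4)
    wt <- (if (c %in% c(2, 4)) fx else 1 - fx) * (if (c %in% c(3, 4)) fy else 1 - fy)
    ok <- xi >= 0 & xi < nx & yi >= 0 & yi < ny & wt > 0
    if (!any(ok)) next
    idx <- xi[ok] + nx * yi[ok] + 1
    s[idx] <- s[idx] + tapply_add(idx, wt[ok] * val[ok])
    w[idx] <- w[idx] + tapply_add(idx, wt[ok])
  }
  list(sum = s, w = w)
}

# sum duplicated indices (scatter-add); returns per unique occurrence of idx
tapply_add <- function(idx, v) {
  out <- rowsum(v, idx)
  out[match(idx, sort(unique(idx)))]
}

#' Flatten motion-corrected samples to a reference surface and merge
#'
#' Every sample's axial position is shifted so the reference surface comes
#' to lie at a constant target depth index; samples from all volumes are
#' then binned into the output grid with trilinear weights and combined by
#' weighted mean, storing per-voxel contribution counts. Holes in the
#' reference surface are interpolated from the nearest valid positions
#' before flattening. Transverse positions are never altered.
#'
#' @param samples list of `corrected_samples`.
#' @param ref an `oct_surface` in the common frame (from [mean_surface()]).
#' @param target_frac target depth of the reference surface as a fraction
#'   of the axial extent (default 75 percent: retina above, choroid margin
#'   below).
#' @param nz output axial voxel count (defaults to the input's).
#' @return a `fused_volume`: `intensity` (NA where no contributions),
#'   `counts`, `target_idx` (0-based row index of the flattened reference),
#'   reference tag and spacings.
#' @export
flatten_and_merge <- function(samples, ref, target_frac = 0.75, nz = NULL) {
  if (!length(samples)) stopf("no samples to merge")
  p <- samples[[1]]$protocol
  dzu <- samples[[1]]$dz_um
  nz_in <- nrow(samples[[1]]$intensity)
  nz <- nz %||% nz_in
  target_idx <- round(target_frac * (nz - 1))
  target_um <- target_idx * dzu
  refd <- fill_holes(ref$depth_um)
  shifts <- lapply(samples, function(s) {
    rd <- bilinear_lookup(refd, s$x_um / p$spacing_um, s$y_um / p$spacing_um)
    target_um - rd
  })
  sc <- scatter_samples(samples, nz, p$n_fast, p$n_bscans, dzu, p$spacing_um,
                        extra_zshift_um = shifts)
  intensity <- sc$sum / sc$wsum
  intensity[sc$wsum <= 0] <- NA_real_
  dim(intensity) <- dim(sc$sum)
  structure(list(intensity = intensity, counts = sc$wsum,
                 target_idx = target_idx, reference = ref$layer,
                 dz_um = dzu, pitch_um = p$spacing_um, protocol = p),
            class = "fused_volume")
}

# bilinear lookup in a 2D map (0-based voxel coords), clamped at edges
bilinear_lookup <- function(m, xv, yv) {
  nx <- nrow(m); ny <- ncol(m)
  xv <- pmin(pmax(xv, 0), nx - 1); yv <- pmin(pmax(yv, 0), ny - 1)
  x0 <- pmin(floor(xv), nx - 2); y0 <- pmin(floor(yv), ny - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- xv - x0; fy <- yv - y0
  i00 <- cbind(x0 + 1, y0 + 1); i10 <- cbind(x0 + 2, y0 + 1)
  i01 <- cbind(x0 + 1, y0 + 2); i11 <- cbind(x0 + 2, y0 + 2)
  (1 - fx) * (1 - fy) * m[i00] + fx * (1 - fy) * m[i10] +
    (1 - fx) * fy * m[i01] + fx * fy * m[i11]
}

#' @export
print.fused_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<fused_volume> %d x %d x %d, %s flattened to depth index %d, %.1f%% covered\n",
              d[2], d[3], d[1], toupper(x$reference), x$target_idx,
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' Re-flatten a set of corrected samples to a different reference surface
#'
#' Convenience wrapper: segments the requested layer on each input volume,
#' averages it under the displacement model, and merges flattened to it.
#'
#' @param volumes list of `raster_volume`s.
#' @param samples the matching list of `corrected_samples`.
#' @param model the `displacement_model` used to build `samples`.
#' @param layer `"brm"` or `"prpe"`.
#' @param ... passed to [flatten_and_merge()].
#' @return a `fused_volume` flattened to `layer`.
#' @export
fuse_to_reference <- function(volumes, samples, model, layer = "brm", ...) {
  surfs <- lapply(volumes, segment_surface, layer = layer)
  ref <- mean_surface(surfs, model)
  flatten_and_merge(samples, ref, ...)
}
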