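#' Options for joint motion estimation
#'
#' Motion is estimated by multi-resolution block-coordinate descent on the
#' inter-volume sum-of-squared-differences objective (log intensities):
#' volumes of one fast-axis direction are resampled against a reference
#' gridded from the motion-corrected volumes of the orthogonal direction,
#' one 3D shift per B-scan (one control point per B-scan period), with the
#' two direction groups alternating. An edge-preserving median filter along
#' the B-scan index regularizes the control points without blurring the
#' step discontinuities left by saccades.
#'
#' @param levels spatial pyramid downsampling factors (fast axis), coarse
#'   to fine.
#' @param sweeps alternation sweeps per level.
#' @param search_tr transverse search half-range of the rigid stage per
#'   level (level voxels).
#' @param search_resid per-B-scan fast-axis residual search half-range per
#'   level (level voxels); wide at the coarsest level so saccade-sized
#'   jumps are captured, tight at fine levels for stability.
#' @param search_ax axial search half-range per level (level voxels).
#' @param order interpolation order of the fitted displacement function in
#'   time: 1 (piecewise linear) or 3 (cubic spline through the control
#'   points).
#' @param mu strength of the second-difference penalty that fuses the
#'   per-B-scan estimates into a smooth displacement function (relative to
#'   the mean per-B-scan confidence).
#' @param median_window window (B-scans) of the edge-preserving filter
#'   applied to the fused control points.
#' @param min_valid_frac minimum fraction of valid (overlapping) voxels a
#'   candidate shift must be scored on.
#' @param tol relative objective decrease below which the multi-resolution
#'   schedule is considered converged.
#' @return a `motion_opts` list.
#' @export
motion_opts <- function(levels = c(4L, 2L, 1L), sweeps = c(2L, 2L, 3L),
                        search_tr = c(3L, 2L, 1L), search_resid = c(3L, 1L, 1L),
                        search_ax = c(3L, 2L, 1L),
                        order = 3L, mu = 2, median_window = 3L,
                        min_valid_frac = 0.25, tol = 1e-6) {
  stopifnot(length(sweeps) == length(levels),
            length(search_tr) == length(levels),
            length(search_resid) == length(levels),
            length(search_ax) == length(levels), order %in% c(1L, 3L))
  structure(list(levels = as.integer(levels), sweeps = as.integer(sweeps),
                 search_tr = as.integer(search_tr),
                 search_resid = as.integer(search_resid),
                 search_ax = as.integer(search_ax), order = as.integer(order),
                 mu = mu,
                 median_window = as.integer(median_window),
                 min_valid_frac = min_valid_frac, tol = tol),
            class = "motion_opts")
}

#' Evaluate a displacement model
#'
#' Continuous interpolation of the per-B-scan control points of one
#' volume; exact at control times.
#'
#' @param model a `displacement_model`.
#' @param volume 1-based volume index.
#' @param t times (s, absolute acquisition time) within the volume's span.
#' @return `length(t) x 3` displacement matrix (um).
#' @export
eval_displacement <- function(model, volume, t) {
  stopifnot(inherits(model, "displacement_model"))
  p <- model$protocol
  t0 <- volume_start(p, volume)
  if (any(t < t0 - 1e-9 | t > t0 + p$vol_duration_s + 1e-9))
    stopf("evaluation time outside volume %d span [%.4g, %.4g] s",
          volume, t0, t0 + p$vol_duration_s)
  ct <- model$times[[volume]]
  dv <- model$disp[[volume]]
  tc <- pmin(pmax(t, ct[1]), ct[length(ct)])
  out <- vapply(1:3, function(ax) {
    if (nrow(dv) < 2) return(rep(dv[1, ax], length(t)))
    if (model$order == 1L) {
      approx(ct, dv[, ax], tc, rule = 2)$y
    } else {
      splinefun(ct, dv[, ax], method = "natural")(tc)
    }
  }, numeric(length(t)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(t))
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.displacement_model <- function(x, ...) {
  cat(sprintf("<displacement_model> %d volumes, %d control points each, order %d\n",
              length(x$disp), nrow(x$disp[[1]]), x$order))
  cat(sprintf("  objective %.6g -> %.6g over %d stages; converged: %s\n",
              x$objective[1], tail(x$objective, 1), length(x$objective) - 1,
              x$converged))
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.displacement_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$disp), function(v)
    tibble(volume = v, time_s = x$times[[v]],
           dx_um = x$disp[[v]][, 1], dy_um = x$disp[[v]][, 2],
           dz_um = x$disp[[v]][, 3])))
}

#' @rdname tidy_methods
#' @export
glance.displacement_model <- function(x, ...) {
  tibble(n_volumes = length(x$disp),
         n_control = nrow(x$disp[[1]]),
         objective = tail(x$objective, 1),
         objective_initial = x$objective[1],
         converged = x$converged)
}

# internal: per-B-scan control values -> per-A-scan displacement matrix is
# done via eval_displacement; here control values are used directly since
# updates operate per B-scan.

# downsample the fast axis and z of a (nz, nfast, nslow) array
down_vol <- function(grid, fz, ffast) downsample_grid(grid, fz, ffast)

# build a leave-group-out reference grid at a pyramid level
build_ref <- function(logs_ds, volumes, disp, include, level, fz,
                      pitch_um, dz_um, nxr, nyr, nzr, wmin = 0.25) {
  sum <- numeric(nzr * nxr * nyr); dim(sum) <- c(nzr, nxr, nyr)
  wsum <- numeric(nzr * nxr * nyr); dim(wsum) <- c(nzr, nxr, nyr)
  unit_tr <- level * pitch_um
  unit_ax <- fz * dz_um
  for (v in include) {
    vol <- volumes[[v]]
    p <- vol$protocol
    ld <- logs_ds[[v]]
    nfc <- dim(ld)[2]
    keep <- which(vol$mask)
    if (!length(keep)) next
    fast_um <- ((seq_len(nfc) - 1) * level + (level - 1) / 2) * p$spacing_um
    slow_um <- (keep - 1) * p$spacing_um
    m <- disp[[v]][keep, , drop = FALSE]
    if (vol$direction == "x") {
      xv <- rep(fast_um, times = length(keep)) - rep(m[, 1], each = nfc)
      yv <- rep(slow_um, each = nfc) - rep(m[, 2], each = nfc)
    } else {
      yv <- rep(fast_um, times = length(keep)) - rep(m[, 2], each = nfc)
      xv <- rep(slow_um, each = nfc) - rep(m[, 1], each = nfc)
    }
    zs <- (-rep(m[, 3], each = nfc)) / unit_ax
    cols <- ld[, , keep, drop = FALSE]
    dim(cols) <- c(dim(ld)[1], nfc * length(keep))
    scatter_cpp(cols, xv / unit_tr, yv / unit_tr, zs, sum, wsum)
  }
  value_grid(sum, wsum, wmin)
}

#' Inter-volume registration objective
#'
#' Mean squared difference of log intensities between each volume's
#' motion-corrected samples and a reference gridded from the other
#' volumes (leave-one-out), averaged over volumes. This is the data term
#' minimized by [estimate_motion()]; it is invariant to a common constant
#' displacement added to all volumes (up to grid-boundary resampling
#' effects), which is why the estimate is gauge-fixed to zero mean.
#'
#' @param volumes list of `raster_volume`s.
#' @param model a `displacement_model`, or `NULL` for zero displacement.
#' @return the scalar objective.
#' @export
registration_objective <- function(volumes, model = NULL) {
  p <- volumes[[1]]$protocol
  dzu <- vol_dz(volumes[[1]])
  nz <- dim(volumes[[1]]$grid)[1]
  disp <- if (is.null(model)) {
    lapply(volumes, function(v) matrix(0, p$n_bscans, 3))
  } else model$disp
  samples <- lapply(seq_along(volumes), function(v) {
    s <- correct_volume_bscan(volumes[[v]], disp[[v]])
    s$intensity <- log1p(s$intensity)
    s
  })
  sc <- scatter_samples(samples, nz, p$n_fast, p$n_bscans, dzu, p$spacing_um,
                        per_volume = TRUE)
  j <- 0; nv <- 0
  for (v in seq_along(samples)) {
    ref <- value_grid(sc$sum - sc$per_volume[[v]]$sum,
                      sc$wsum - sc$per_volume[[v]]$wsum)
    s <- samples[[v]]
    got <- gather_cpp(ref, nrow(s$intensity), s$x_um / p$spacing_um,
                      s$y_um / p$spacing_um,
                      rep(s$z_off_um, length.out = ncol(s$intensity)) / dzu)
    d2 <- (s$intensity - got)^2
    ok <- is.finite(d2)
    j <- j + sum(d2[ok]); nv <- nv + sum(ok)
  }
  j / max(nv, 1)
}

# correction with per-B-scan constant displacement (control values)
correct_volume_bscan <- function(volume, m) {
  p <- volume$protocol
  keep <- which(volume$mask)
  pos <- nominal_positions(volume)
  sel <- as.vector(outer(seq_len(p$n_fast), (keep - 1) * p$n_fast, `+`))
  grid <- volume$grid
  dim(grid) <- c(dim(grid)[1], p$n_fast * p$n_bscans)
  mk <- m[rep(keep, each = p$n_fast), , drop = FALSE]
  structure(list(intensity = grid[, sel, drop = FALSE],
                 x_um = pos$x[sel] - mk[, 1],
                 y_um = pos$y[sel] - mk[, 2],
                 z_off_um = -mk[, 3],
                 bscan = rep(keep, each = p$n_fast),
                 volume = volume$index, direction = volume$direction,
                 dz_um = vol_dz(volume), pitch_um = p$spacing_um,
                 protocol = p), class = "corrected_samples")
}

#' Jointly estimate per-volume eye motion from orthogonal raster volumes
#'
#' Estimates, for every volume, a time-continuous 3D displacement function
#' (one control point per B-scan period) by minimizing the squared
#' log-intensity difference between each volume resampled at
#' displacement-corrected positions and a reference built from the
#' orthogonally scanned volumes, coarse-to-fine. The unobservable common
#' offset is gauge-fixed: the mean displacement across all volumes is
#' constrained to zero per axis. The objective is evaluated at full
#' resolution after every pyramid stage and a stage is rolled back if it
#' did not improve, so the reported objective trace is non-increasing.
#'
#' @param volumes list of >= 2 `raster_volume`s with both fast-axis
#'   directions represented; blink masks should already be applied.
#' @param opts a [motion_opts()].
#' @return a `displacement_model` with fields `times`, `disp` (per-volume
#'   control points, um), `order`, `objective` (trace across stages) and
#'   `converged`.
#' @export
estimate_motion <- function(volumes, opts = motion_opts()) {
  usable <- vapply(volumes, function(v) sum(v$mask) > 0, logical(1))
  if (sum(usable) < 2) stopf("fewer than 2 usable volumes")
  dirs <- vapply(volumes, `[[`, character(1), "direction")
  if (length(unique(dirs[usable])) < 2)
    stopf("both fast-axis directions must be represented")
  p <- volumes[[1]]$protocol
  pitch <- p$spacing_um
  dzu <- vol_dz(volumes[[1]])
  nz <- dim(volumes[[1]]$grid)[1]
  nvol <- length(volumes)
  # mild blur tames speckle-driven peak locking of the SSD minima
  logs <- lapply(volumes, function(v) blur_bscans(log1p(v$grid), 0.8))
  ctrl_t <- lapply(seq_len(nvol), function(v) colMeans(volumes[[v]]$times))
  disp <- lapply(seq_len(nvol), function(v) matrix(0, p$n_bscans, 3))

  mk_model <- function(d, obj, conv) {
    structure(list(times = ctrl_t, disp = d, order = opts$order,
                   protocol = p, objective = obj, converged = conv,
                   opts = opts), class = "displacement_model")
  }
  # stage objectives are evaluated on a 2x-downsampled pyramid: the same
  # quantity up to resolution, at a fraction of the cost
  logs_obj <- lapply(logs, down_vol, fz = 2L, ffast = 2L)
  obj_of <- function(d) stage_objective(logs_obj, volumes, d, pitch, dzu)

  obj_trace <- obj_of(disp)
  for (li in seq_along(opts$levels)) {
    lev <- opts$levels[li]
    fz <- if (lev > 1L) 2L else 1L
    nzr <- nz %/% fz
    ngrid <- p$n_fast  # square field: common transverse extent in voxels
    nxr <- ngrid %/% lev
    nyr <- nxr
    logs_ds <- lapply(logs, down_vol, fz = fz, ffast = lev)
    dtry <- disp
    for (sw in seq_len(opts$sweeps[li])) {
      for (grp in c("x", "y")) {
        other <- which(dirs != grp & usable)
        mine <- which(dirs == grp & usable)
        if (!length(other) || !length(mine)) next
        ref <- build_ref(logs_ds, volumes, dtry, other, lev, fz,
                         pitch, dzu, nxr, nyr, nzr)
        for (v in mine) {
          dtry[[v]] <- update_bscans(logs_ds[[v]], volumes[[v]], dtry[[v]],
                                     ref, lev, fz, pitch, dzu, opts)
        }
        # gauge: zero mean displacement across all volumes, per axis
        mu <- colMeans(do.call(rbind, dtry[usable]))
        for (v in which(usable)) dtry[[v]] <- sweep(dtry[[v]], 2, mu)
      }
    }
    jnew <- obj_of(dtry)
    if (jnew <= tail(obj_trace, 1)) {
      disp <- dtry
      obj_trace <- c(obj_trace, jnew)
    } else {
      obj_trace <- c(obj_trace, tail(obj_trace, 1))
    }
  }
  rel <- if (length(obj_trace) >= 2 && obj_trace[1] > 0) {
    (obj_trace[length(obj_trace) - 1] - tail(obj_trace, 1)) / obj_trace[1]
  } else 0
  converged <- is.finite(rel) && abs(rel) < max(opts$tol, 1e-2)
  if (!converged)
    warning("motion estimation did not converge; returning best iterate",
            call. = FALSE)
  mk_model(disp, obj_trace, converged)
}

# one block-coordinate pass over the B-scans of a volume at a pyramid level:
# (1) rigid 3D alignment of the whole volume from the aggregate SSD over
# all B-scans, then (2) a tight per-B-scan residual search with a
# sequential smoothness prior (drift is continuous; the prior is weak
# enough that a well-supported step survives the data term).
update_bscans <- function(ld, vol, m, ref, lev, fz, pitch, dzu, opts) {
  p <- vol$protocol
  li <- match(lev, opts$levels)
  rtr <- opts$search_tr[li]; rax <- opts$search_ax[li]
  rres <- opts$search_resid[li]
  unit_tr <- lev * pitch; unit_ax <- fz * dzu
  nfc <- dim(ld)[2]
  fast_um <- ((seq_len(nfc) - 1) * lev + (lev - 1) / 2) * p$spacing_um
  jset <- which(vol$mask)
  bscan_geom <- function(j, s0) {
    slow_um <- (j - 1) * p$spacing_um
    if (vol$direction == "x") {
      list(xs = (fast_um - s0[1]) / unit_tr,
           ys = rep((slow_um - s0[2]) / unit_tr, nfc),
           zoff = -s0[3] / unit_ax)
    } else {
      list(ys = (fast_um - s0[2]) / unit_tr,
           xs = rep((slow_um - s0[1]) / unit_tr, nfc),
           zoff = -s0[3] / unit_ax)
    }
  }
  # --- rigid stage: common shift over candidates +/- rtr (tr), +/- rax (ax)
  offs_tr <- seq(-rtr, rtr); offs_ax <- seq(-rax, rax)
  agg_ssd <- 0; agg_n <- 0
  for (j in jset) {
    g <- bscan_geom(j, m[j, ])
    res <- ssd_search_cpp(ld[, , j], g$xs, g$ys, g$zoff, ref,
                          offs_tr, offs_tr, offs_ax)
    agg_ssd <- agg_ssd + res$ssd; agg_n <- agg_n + res$n
  }
  norm <- agg_ssd / pmax(agg_n, 1)
  norm[agg_n < opts$min_valid_frac * max(agg_n)] <- Inf
  if (any(is.finite(norm))) {
    pk <- best_with_subvox(norm, offs_tr, offs_tr, offs_ax)
    rigid <- -c(pk[1] * unit_tr, pk[2] * unit_tr, pk[3] * unit_ax)
    m <- sweep(m, 2, -rigid)  # add rigid delta to every B-scan
  }
  # --- slow-axis stage: a single B-scan barely constrains its own
  # slow-axis position (layered structure is nearly shift-invariant along
  # the slow axis), so the slow-axis drift is estimated from overlapping
  # windows of B-scans, each aggregated into one well-conditioned search,
  # and interpolated across the volume.
  # at full resolution speckle dominates the slow-axis SSD contrast, so
  # the windowed stage runs on the speckle-averaged pyramid levels only
  slow_ax <- if (vol$direction == "x") 2L else 1L
  nb0 <- length(jset)
  if (nb0 >= 8 && lev > 1L) {
    W <- max(5L, ceiling(nb0 / 8))
    starts <- unique(pmin(seq(1L, nb0, by = max(2L, W %/% 2)), nb0 - W + 1L))
    cen <- numeric(0); del <- numeric(0); wcf <- numeric(0)
    for (st in starts) {
      win <- jset[st:(st + W - 1L)]
      agg <- 0; aggn <- 0
      offs_sw <- seq(-max(rtr, 3L), max(rtr, 3L))
      # fine axial offsets, marginalized out below: axial misalignment
      # leaks into the slow axis through the layer slope otherwise
      oz_marg <- seq(-0.5, 0.5, by = 0.25)
      for (j in win) {
        g <- bscan_geom(j, m[j, ])
        ox <- if (slow_ax == 1L) offs_sw else 0L
        oy <- if (slow_ax == 2L) offs_sw else 0L
        res <- ssd_search_cpp(ld[, , j], g$xs, g$ys, g$zoff, ref, ox, oy,
                              oz_marg)
        agg <- agg + res$ssd; aggn <- aggn + res$n
      }
      norm <- agg / pmax(aggn, 1)
      # candidates pushing the window outside the reference lose voxels
      # and are not comparable; demand near-complete support
      norm[aggn < 0.8 * max(aggn)] <- Inf
      if (!any(is.finite(norm))) next
      prof <- apply(norm, slow_ax, min)
      i <- which.min(prof)
      sub <- if (i > 1 && i < length(prof) && is.finite(prof[i - 1]) &&
                 is.finite(prof[i + 1])) {
        parabolic_offset(prof[i - 1], prof[i], prof[i + 1])
      } else 0
      cv <- if (i > 1 && i < length(prof) && is.finite(prof[i - 1]) &&
                is.finite(prof[i + 1])) {
        max(prof[i - 1] - 2 * prof[i] + prof[i + 1], 0)
      } else 0
      cen <- c(cen, mean(win))
      del <- c(del, -(offs_sw[i] + sub) * unit_tr)
      wcf <- c(wcf, cv * max(aggn))
    }
    if (length(cen) >= 2) {
      # robust smooth over window centres before interpolation, so one bad
      # (typically edge) window cannot bend the whole trace
      del_s <- smooth_controls(del, wcf + 1e-12, opts$mu, rep(0, length(del)))
      adj <- approx(cen, del_s, seq_len(nrow(m)), rule = 2)$y
      m[, slow_ax] <- m[, slow_ax] + adj
    } else if (length(cen) == 1) {
      m[, slow_ax] <- m[, slow_ax] + del
    }
  }
  # --- residual stage: per-B-scan estimates with per-axis confidence
  # (SSD curvature), fused by a second-difference penalized least-squares
  # fit per axis. The fast-axis shift and the axial shift are well
  # conditioned within a single B-scan; the slow-axis component is frozen
  # here (it is handled by the windowed stage above).
  offs1 <- seq(-rres, rres, by = 0.5)  # half-voxel steps reduce peak locking
  offs_slow <- 0L
  if (vol$direction == "x") {
    offs_x <- offs1; offs_y <- offs_slow
  } else {
    offs_x <- offs_slow; offs_y <- offs1
  }
  nb <- nrow(m)
  raw <- m
  conf <- matrix(0, nb, 3)
  units <- c(unit_tr, unit_tr, unit_ax)
  offs_ax2 <- seq(-rax, rax, by = 0.5)  # half-voxel axial sampling
  for (j in jset) {
    s0 <- m[j, ]
    g <- bscan_geom(j, s0)
    res <- ssd_search_cpp(ld[, , j], g$xs, g$ys, g$zoff, ref,
                          offs_x, offs_y, offs_ax2)
    n <- res$n
    norm <- res$ssd / pmax(n, 1L)
    norm[n < opts$min_valid_frac * max(n)] <- Inf
    if (!any(is.finite(norm))) next
    # per-axis minima of the profile with the other axes marginalized out,
    # so axial misalignment cannot leak into the transverse estimate (and
    # vice versa) through the layer slope
    offs_all <- list(offs_x, offs_y, offs_ax2)
    for (ax in 1:3) {
      if (length(offs_all[[ax]]) < 3) next
      prof <- apply(norm, ax, min)
      pm <- profile_min(prof, offs_all[[ax]])
      if (!is.na(pm[1])) {
        raw[j, ax] <- s0[ax] - pm[1] * units[ax]
        conf[j, ax] <- pm[2] / units[ax]^2  # per um^2
      }
    }
  }
  # per-axis fusion: min sum conf_j (m_j - raw_j)^2 + mu sum (d2 m)^2
  mnew <- m
  for (ax in 1:3) {
    mnew[, ax] <- smooth_controls(raw[, ax], conf[, ax], opts$mu, m[, ax],
                                  step_thresh = 1.5 * units[ax])
  }
  mnew
}

# minimum of a 1D SSD profile with parabolic refinement; returns
# c(position, curvature) or c(NA, 0) when unusable
profile_min <- function(prof, offs) {
  i <- which.min(prof)
  if (!is.finite(prof[i])) return(c(NA_real_, 0))
  if (i == 1 || i == length(prof) ||
      !is.finite(prof[i - 1]) || !is.finite(prof[i + 1]))
    return(c(offs[i], 0))
  step <- offs[2] - offs[1]
  sub <- parabolic_offset(prof[i - 1], prof[i], prof[i + 1])
  cv <- max(prof[i - 1] - 2 * prof[i] + prof[i + 1], 0) / step^2
  c(offs[i] + sub * step, cv)
}

# per-axis curvature of the SSD lattice at its minimum (finite differences)
curvature3 <- function(norm) {
  ix <- arrayInd(which.min(norm), dim(norm))
  out <- numeric(3)
  for (ax in 1:3) {
    i <- ix[ax]
    if (i > 1 && i < dim(norm)[ax]) {
      im <- ix; im[ax] <- i - 1
      ip <- ix; ip[ax] <- i + 1
      c2 <- norm[im[1], im[2], im[3]] - 2 * norm[ix[1], ix[2], ix[3]] +
        norm[ip[1], ip[2], ip[3]]
      if (is.finite(c2) && c2 > 0) out[ax] <- c2
    }
  }
  out
}

# confidence-weighted second-difference smoothing of a control-point
# series, with one outlier-downweighting pass; fall_back fills positions
# with no usable data
smooth_controls <- function(raw, conf, mu, fall_back, step_thresh = NULL) {
  n <- length(raw)
  if (n < 3 || all(conf <= 0)) return(fall_back)
  d <- ifelse(conf > 0, raw, fall_back)
  # saccades leave genuine steps in the series: detect them on a median
  # prefilter and fit the penalized smoother per segment, so the
  # second-difference penalty never bridges (and flattens) a step
  segs <- list(seq_len(n))
  if (!is.null(step_thresh) && n >= 9) {
    med <- run_med(d, 5L)
    jumps <- which(abs(diff(med)) > step_thresh)
    jumps <- jumps[jumps >= 4 & jumps <= n - 4]
    if (length(jumps)) {
      jumps <- jumps[c(TRUE, diff(jumps) > 4)]
      bounds <- c(0, jumps, n)
      segs <- lapply(seq_len(length(bounds) - 1), function(k)
        (bounds[k] + 1):bounds[k + 1])
    }
  }
  out <- numeric(n)
  for (seg in segs) {
    ns <- length(seg)
    ds <- d[seg]; cs <- conf[seg]
    if (ns < 3 || all(cs <= 0)) { out[seg] <- ds; next }
    D <- diff(diag(ns), differences = 2)
    L <- crossprod(D)
    solve_once <- function(w) {
      A <- diag(w, ns) + mu * mean(w[w > 0]) * L + diag(1e-9 * max(w), ns)
      as.numeric(solve(A, w * ds))
    }
    fit <- solve_once(cs)
    # downweight gross outliers against the smooth fit and re-solve
    resid <- abs(ds - fit)
    s <- median(resid[cs > 0]) * 4 + 1e-9
    w2 <- cs / (1 + (resid / s)^2)
    out[seg] <- solve_once(w2)
  }
  out
}

# minimizing index of a 3D SSD lattice with per-axis parabolic refinement
best_with_subvox <- function(norm, o1, o2, o3) {
  ix <- arrayInd(which.min(norm), dim(norm))
  sub <- numeric(3)
  for (ax in 1:3) {
    i <- ix[ax]
    if (i > 1 && i < dim(norm)[ax]) {
      idx_m <- ix; idx_m[ax] <- i - 1
      idx_p <- ix; idx_p[ax] <- i + 1
      ym1 <- norm[idx_m[1], idx_m[2], idx_m[3]]
      yp1 <- norm[idx_p[1], idx_p[2], idx_p[3]]
      y0 <- norm[ix[1], ix[2], ix[3]]
      if (is.finite(ym1) && is.finite(yp1))
        sub[ax] <- parabolic_offset(ym1, y0, yp1)
    }
  }
  c(o1[ix[1]] + sub[1], o2[ix[2]] + sub[2], o3[ix[3]] + sub[3])
}


# leave-one-out SSD objective evaluated on 2x-downsampled log volumes
stage_objective <- function(logs_ds, volumes, disp, pitch, dzu) {
  p <- volumes[[1]]$protocol
  nzr <- dim(logs_ds[[1]])[1]
  nxr <- p$n_fast %/% 2L
  j <- 0; nv <- 0
  for (v in seq_along(volumes)) {
    others <- setdiff(seq_along(volumes), v)
    ref <- build_ref(logs_ds, volumes, disp, others, 2L, 2L, pitch, dzu,
                     nxr, nxr, nzr)
    vol <- volumes[[v]]
    ld <- logs_ds[[v]]
    nfc <- dim(ld)[2]
    keep <- which(vol$mask)
    if (!length(keep)) next
    fast_um <- ((seq_len(nfc) - 1) * 2 + 0.5) * p$spacing_um
    slow_um <- (keep - 1) * p$spacing_um
    m <- disp[[v]][keep, , drop = FALSE]
    if (vol$direction == "x") {
      xv <- rep(fast_um, times = length(keep)) - rep(m[, 1], each = nfc)
      yv <- rep(slow_um, each = nfc) - rep(m[, 2], each = nfc)
    } else {
      yv <- rep(fast_um, times = length(keep)) - rep(m[, 2], each = nfc)
      xv <- rep(slow_um, each = nfc) - rep(m[, 1], each = nfc)
    }
    zs <- (-rep(m[, 3], each = nfc)) / (2 * dzu)
    cols <- ld[, , keep, drop = FALSE]
    dim(cols) <- c(nzr, nfc * length(keep))
    got <- gather_cpp(ref, nzr, xv / (2 * pitch), yv / (2 * pitch), zs)
    d2 <- (cols - got)^2
    ok <- is.finite(d2)
    j <- j + sum(d2[ok]); nv <- nv + sum(ok)
  }
  j / max(nv, 1)
}

# per-B-scan 2D Gaussian blur (depth x fast axis)
blur_bscans <- function(grid, sigma) {
  if (sigma <= 0) return(grid)
  for (j in seq_len(dim(grid)[3]))
    grid[, , j] <- EBImage::imageData(EBImage::gblur(grid[, , j], sigma = sigma))
  grid
}
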