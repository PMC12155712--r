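#' Estimate smooth per-B-scan illumination gain curves
#'
#' Models the illumination bias of each volume as a positive gain that
#' varies smoothly along every B-scan's fast axis (a small number of
#' control points, linearly interpolated). The gain of each volume is
#' estimated from the log-intensity disagreement between its
#' motion-corrected A-scans and the mean reference gridded from all
#' volumes; continuity along the slow axis arises implicitly because the
#' reference includes the orthogonally scanned volumes. The small
#' control-point count band-limits the gain so genuine image features
#' (which vary quickly along the fast axis) cannot be absorbed.
#'
#' Only relative gains between volumes are observable; the estimate is
#' gauge-fixed so the per-position mean log gain across volumes is zero,
#' which makes apply-then-re-estimate a fixed point. Use
#' [gain_field_image()] to compare gains across volumes in the common
#' transverse frame.
#'
#' @param samples list of `corrected_samples` (one per volume), already
#'   motion-corrected so overlapping positions are comparable.
#' @param n_ctrl control points per B-scan along the fast axis.
#' @param noise_floor intensities below this are ignored in the fit.
#' @param max_log_step maximum |log-gain| change allowed between adjacent
#'   control points (smoothness bound).
#' @param min_overlap minimum fraction of A-scans that must have a
#'   cross-volume reference value.
#' @return a `gain_field`: per-volume `n_ctrl x n_bscans` gain control
#'   matrices (`curves`), per-volume global `scale` factors (unity here;
#'   see [match_brightness()]), and geometry.
#' @export
estimate_gain <- function(samples, n_ctrl = 8L, noise_floor = 0.08,
                          max_log_step = 0.5, min_overlap = 0.25) {
  stopifnot(length(samples) >= 2, n_ctrl >= 2)
  p <- samples[[1]]$protocol
  dzu <- samples[[1]]$dz_um
  nz <- nrow(samples[[1]]$intensity)
  logt <- function(x) log(pmax(x, 1e-6))
  sc <- scatter_samples(lapply(samples, function(s) {
    s$intensity <- logt(s$intensity); s
  }), nz, p$n_fast, p$n_bscans, dzu, p$spacing_um)
  ref <- value_grid(sc$sum, sc$wsum)
  curves <- vector("list", length(samples))
  for (v in seq_along(samples)) {
    s <- samples[[v]]
    got <- gather_cpp(ref, nz, s$x_um / p$spacing_um, s$y_um / p$spacing_um,
                      s$z_off_um / dzu)
    li <- logt(s$intensity)
    use <- is.finite(got) & s$intensity > noise_floor & exp(got) > noise_floor
    # per-A-scan robust log-gain: median over valid depths of log(I) - log(ref)
    dcol <- li - got
    dcol[!use] <- NA
    nA <- ncol(li)
    delta <- rep(NA_real_, nA)
    nval <- colSums(use)
    has <- nval >= 8
    if (any(has)) delta[has] <- apply(dcol[, has, drop = FALSE], 2, median, na.rm = TRUE)
    if (mean(has) < min_overlap)
      stopf("insufficient cross-volume overlap for gain estimation (%.0f%% of A-scans)",
            100 * mean(has))
    # fit n_ctrl-point curve per B-scan by weighted least squares on a
    # linear interpolation basis (hat functions along the fast axis)
    nb <- p$n_bscans
    nfast <- p$n_fast
    knots <- seq(0, nfast - 1, length.out = n_ctrl)
    fi <- (seq_len(nfast) - 1)
    B <- hat_basis(fi, knots)
    cm <- matrix(0, n_ctrl, nb)
    dmat <- matrix(delta, nfast, nb)
    wmat <- matrix(ifelse(is.na(delta), 0, pmin(nval, 64)), nfast, nb)
    dmat[is.na(dmat)] <- 0
    # average the per-A-scan deltas over one control interval before the
    # fit: variation faster than the control spacing is image feature, not
    # illumination, and must not bleed into the edge control points
    h <- max(1L, nfast %/% (2L * n_ctrl))
    if (nfast > 4L * h) {
      for (hh in c(h, 1L)) {  # two passes suppress parity patterns
        for (j in seq_len(nb)) {
          sm <- run_wmean(dmat[, j], wmat[, j], hh)
          dmat[, j] <- sm$mean
          wmat[, j] <- sm$weight
        }
      }
    }
    for (j in seq_len(nb)) {
      w <- wmat[, j]
      if (sum(w > 0) < n_ctrl) { cm[, j] <- 0; next }
      BW <- B * w
      A <- crossprod(BW, B) + diag(1e-6, n_ctrl)
      cm[, j] <- solve(A, crossprod(BW, dmat[, j]))
    }
    # the bias varies slowly across B-scans as well (consecutive B-scans
    # are acquired milliseconds apart): smooth control values along the
    # slow axis to suppress speckle noise in the fit
    wlen <- min(15L, max(3L, (nb %/% 8) * 2L + 1L))
    if (nb >= wlen && wlen >= 3) {
      kern <- rep(1 / wlen, wlen)
      for (k in seq_len(n_ctrl)) {
        padded <- c(rev(cm[k, seq_len(wlen)]), cm[k, ], cm[k, nb - seq_len(wlen) + 1])
        sm <- stats::filter(padded, kern, sides = 2)
        cm[k, ] <- as.numeric(sm)[(wlen + 1):(wlen + nb)]
      }
    }
    # smoothness bound on log-gain steps between control points
    for (j in seq_len(nb)) {
      for (k in 2:n_ctrl) {
        st <- cm[k, j] - cm[k - 1, j]
        if (abs(st) > max_log_step)
          cm[k, j] <- cm[k - 1, j] + sign(st) * max_log_step
      }
    }
    curves[[v]] <- exp(cm)
  }
  structure(list(curves = curves, scale = rep(1, length(samples)),
                 n_ctrl = as.integer(n_ctrl), protocol = p,
                 directions = vapply(samples, `[[`, character(1), "direction")),
            class = "gain_field")
}

# weighted running mean with edge-shrinking windows (cumsum based)
run_wmean <- function(x, w, h) {
  n <- length(x)
  cw <- c(0, cumsum(w))
  cxw <- c(0, cumsum(x * w))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  W <- cw[hi + 1] - cw[lo]
  S <- cxw[hi + 1] - cxw[lo]
  m <- ifelse(W > 0, S / W, 0)
  list(mean = m, weight = W / (hi - lo + 1))
}

#' Dense transverse gain map of one volume in the common frame
#'
#' Expands the per-B-scan control-point curve into an `n_fast x n_bscans`
#' multiplicative gain image indexed (x, y) regardless of the volume's
#' fast-axis direction.
#'
#' @param gain a `gain_field`.
#' @param volume 1-based volume index.
#' @return numeric matrix (x by y).
#' @export
gain_field_image <- function(gain, volume) {
  p <- gain$protocol
  cm <- gain$curves[[volume]]
  knots <- seq(0, p$n_fast - 1, length.out = gain$n_ctrl)
  B <- hat_basis(seq_len(p$n_fast) - 1, knots)
  dense <- B %*% cm  # fast x slow
  dir <- gain$directions[volume] %||% "x"
  if (dir == "x") dense else t(dense)
}

# hat-function (linear B-spline) basis evaluated at x for given knots
hat_basis <- function(x, knots) {
  n <- length(knots)
  B <- matrix(0, length(x), n)
  for (k in seq_len(n)) {
    if (k > 1) {
      w <- (x - knots[k - 1]) / (knots[k] - knots[k - 1])
      B[, k] <- B[, k] + pmax(0, pmin(w, 1)) * (x <= knots[k]) * (x > knots[k - 1])
    }
    if (k < n) {
      w <- (knots[k + 1] - x) / (knots[k + 1] - knots[k])
      B[, k] <- B[, k] + pmax(0, pmin(w, 1)) * (x >= knots[k]) * (x < knots[k + 1])
    }
  }
  B[x <= knots[1], 1] <- 1
  B[x >= knots[n], n] <- 1
  B
}

# evaluate a volume's gain at every A-scan of a corrected_samples object
gain_at_samples <- function(gain, s) {
  p <- gain$protocol
  cm <- gain$curves[[s$volume]]
  knots <- seq(0, p$n_fast - 1, length.out = gain$n_ctrl)
  fast_idx <- rep(seq_len(p$n_fast) - 1, length.out = ncol(s$intensity))
  B <- hat_basis(fast_idx, knots)
  rowSums(B * t(cm[, s$bscan, drop = FALSE]))
}

#' Apply an estimated gain field to corrected samples
#'
#' Intensities are divided by the per-A-scan gain (and multiplied by the
#' volume's global brightness scale); positions are untouched.
#'
#' @param samples a `corrected_samples` object.
#' @param gain a `gain_field` from [estimate_gain()].
#' @return the samples with adjusted intensities.
#' @export
apply_gain <- function(samples, gain) {
  stopifnot(inherits(samples, "corrected_samples"), inherits(gain, "gain_field"))
  g <- gain_at_samples(gain, samples)
  if (any(g <= 0)) stopf("gain must be positive everywhere")
  samples$intensity <- sweep(samples$intensity, 2,
                             gain$scale[samples$volume] / g, `*`)
  samples
}

#' Match overall volume brightness toward the brightest volume
#'
#' Computes per-volume robust mean intensities (mean of above-noise voxels
#' between each volume's own median and 90th percentile, which makes the
#' statistic exactly scale-equivariant) and returns the factors that scale
#' every volume up to the brightest one: the brightest volume gets scale 1
#' and all scales are >= 1.
#'
#' @param samples list of `corrected_samples`.
#' @return numeric vector of per-volume scale factors.
#' @export
match_brightness <- function(samples) {
  stopifnot(length(samples) >= 2)
  rmean <- vapply(samples, function(s) {
    v <- as.numeric(s$intensity)
    q <- quantile(v, c(0.5, 0.9), names = FALSE)
    mean(v[v >= q[1] & v <= q[2]])
  }, numeric(1))
  max(rmean) / rmean
}

#' Attach brightness scales to a gain field
#' @param gain a `gain_field`.
#' @param scales per-volume factors from [match_brightness()].
#' @return the updated `gain_field`.
#' @export
set_brightness_scales <- function(gain, scales) {
  stopifnot(inherits(gain, "gain_field"),
            length(scales) == length(gain$curves))
  gain$scale <- scales
  gain
}

#' @export
print.gain_field <- function(x, ...) {
  rng <- range(unlist(x$curves))
  cat(sprintf("<gain_field> %d volumes, %d control points/B-scan, gain range [%.3f, %.3f], scales %s\n",
              length(x$curves), x$n_ctrl, rng[1], rng[2],
              paste(sprintf("%.2f", x$scale), collapse = ", ")))
  invisible(x)
}

#' @rdname tidy_methods
#' @export
tidy.gain_field <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$curves), function(v) {
    cm <- x$curves[[v]]
    tibble(volume = v,
           bscan = rep(seq_len(ncol(cm)), each = nrow(cm)),
           ctrl = rep(seq_len(nrow(cm)), ncol(cm)),
           gain = as.numeric(cm))
  }))
}
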