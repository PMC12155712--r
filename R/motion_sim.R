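#' Eye-motion model parameters
#'
#' Fixational eye motion is modelled as the sum of a slow drift (integrated
#' Gaussian random walk, independent per axis) and ballistic microsaccades
#' (a Poisson process of instantaneous transverse jumps). Axial drift uses
#' its own, typically smaller, diffusion coefficient.
#'
#' @param drift_sd_um_rts transverse drift diffusion (um per sqrt second),
#'   applied independently to x and y.
#' @param axial_sd_um_rts axial drift diffusion (um per sqrt second).
#' @param saccade_rate_hz expected saccade count per second.
#' @param saccade_amp_um mean saccade amplitude (um).
#' @param saccade_amp_sd_um sd of the saccade amplitude (um).
#' @return a `motion_params` object.
#' @export
motion_params <- function(drift_sd_um_rts = 10, axial_sd_um_rts = 2,
                          saccade_rate_hz = 0, saccade_amp_um = 60,
                          saccade_amp_sd_um = 15) {
  stopifnot(drift_sd_um_rts >= 0, axial_sd_um_rts >= 0,
            saccade_rate_hz >= 0, saccade_amp_um >= 0, saccade_amp_sd_um >= 0)
  structure(list(drift_sd_um_rts = drift_sd_um_rts,
                 axial_sd_um_rts = axial_sd_um_rts,
                 saccade_rate_hz = saccade_rate_hz,
                 saccade_amp_um = saccade_amp_um,
                 saccade_amp_sd_um = saccade_amp_sd_um),
            class = "motion_params")
}

#' Simulate a time-continuous 3D eye-displacement trace
#'
#' The trace gives the apparent displacement of the retina in the scanner
#' frame: an A-scan aimed at nominal position `p` at time `t` samples the
#' tissue at `p - d(t)`. Drift is integrated at 1 ms resolution and stored
#' as piecewise-linear knots; saccades appear as step discontinuities
#' (duplicated knots) at their event times.
#'
#' @param duration_s trace duration; evaluation is defined on
#'   `[0, duration_s]`.
#' @param params a [motion_params()].
#' @param seed random seed.
#' @param resolution_s knot spacing of the integrated drift.
#' @return a `motion_trace` with fields `t` (knot times), `d` (knots x 3
#'   displacement matrix, um; columns x, y, z) and `saccade_times`.
#' @export
simulate_motion <- function(duration_s, params = motion_params(), seed = 1L,
                            resolution_s = 1e-3) {
  stopifnot(duration_s > 0, inherits(params, "motion_params"))
  set.seed(seed)
  n <- max(2L, ceiling(duration_s / resolution_s) + 1L)
  tt <- seq(0, duration_s, length.out = n)
  dt <- tt[2] - tt[1]
  sds <- c(params$drift_sd_um_rts, params$drift_sd_um_rts, params$axial_sd_um_rts)
  d <- vapply(sds, function(s) {
    if (s == 0) rep(0, n) else c(0, cumsum(rnorm(n - 1, 0, s * sqrt(dt))))
  }, numeric(n))

  sac_t <- numeric(0)
  if (params$saccade_rate_hz > 0) {
    k <- rpois(1, params$saccade_rate_hz * duration_s)
    if (k > 0) {
      sac_t <- sort(runif(k, 0, duration_s))
      for (ts in sac_t) {
        amp <- abs(rnorm(1, params$saccade_amp_um, params$saccade_amp_sd_um))
        ang <- runif(1, 0, 2 * pi)
        jump <- c(cos(ang), sin(ang), 0) * amp
        pre <- c(approx(tt, d[, 1], ts, rule = 2)$y,
                 approx(tt, d[, 2], ts, rule = 2)$y,
                 approx(tt, d[, 3], ts, rule = 2)$y)
        after <- tt > ts
        d[after, ] <- sweep(d[after, , drop = FALSE], 2, jump, `+`)
        # duplicated knots make the step exact at the saccade time
        d <- rbind(d[!after, , drop = FALSE], pre, pre + jump,
                   d[after, , drop = FALSE])
        tt <- c(tt[!after], ts, ts + 1e-9, tt[after])
      }
    }
  }
  structure(list(t = tt, d = unname(d), saccade_times = sac_t,
                 duration_s = duration_s, params = params, seed = seed),
            class = "motion_trace")
}

#' Constant (or zero) motion trace
#' @param duration_s trace duration (s).
#' @param d_um length-3 constant displacement (um).
#' @return a `motion_trace`.
#' @export
constant_trace <- function(duration_s, d_um = c(0, 0, 0)) {
  structure(list(t = c(0, duration_s),
                 d = rbind(d_um, d_um, deparse.level = 0),
                 saccade_times = numeric(0), duration_s = duration_s,
                 params = NULL, seed = NA_integer_),
            class = "motion_trace")
}

#' Evaluate a motion trace
#'
#' Piecewise-linear interpolation between knots; continuous between
#' saccades, stepping at saccade times.
#'
#' @param trace a `motion_trace`.
#' @param t times (s) within the trace duration.
#' @return a `length(t) x 3` displacement matrix (um).
#' @export
eval_trace <- function(trace, t) {
  stopifnot(inherits(trace, "motion_trace"))
  if (any(t < -1e-9 | t > trace$duration_s + 1e-9))
    stopf("trace evaluated outside [0, %g] s", trace$duration_s)
  out <- vapply(1:3, function(ax)
    approx(trace$t, trace$d[, ax], pmin(pmax(t, 0), trace$duration_s),
           rule = 2, ties = "ordered")$y, numeric(length(t)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(t))
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.motion_trace <- function(x, ...) {
  rng <- apply(x$d, 2, function(v) diff(range(v)))
  cat(sprintf("<motion_trace> %.3g s, %d knots, %d saccades; p-p range %.1f/%.1f/%.1f um\n",
              x$duration_s, length(x$t), length(x$saccade_times),
              rng[1], rng[2], rng[3]))
  invisible(x)
}

#' @rdname autoplot_methods
#' @export
autoplot.motion_trace <- function(object, ...) {
  df <- tibble(t = rep(object$t, 3),
               axis = rep(c("x", "y", "z"), each = length(object$t)),
               displacement_um = c(object$d))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$displacement_um,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "displacement (µm)")
}
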