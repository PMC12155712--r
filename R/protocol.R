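#' Acquisition protocol for multi-volume orthogonal raster scanning
#'
#' Describes the scan geometry and timing of a multi-volume acquisition in
#' which consecutive volumes alternate their fast-axis direction between x
#' and y. The defaults reproduce the high-resolution prototype protocol:
#' 6 x 6 mm field, 500 x 500 A-scans (12 um transverse spacing), 2.4 s per
#' volume, six volumes in 14.6 s total.
#'
#' Per-A-scan timestamps follow
#' `t = volume start + bscan * bscan_period + ascan / ascan_rate_hz`,
#' with `bscan_period = vol_duration_s / n_bscans` (fast-axis flyback is
#' folded into the B-scan period) and volume starts separated by
#' `vol_duration_s + gap_s`.
#'
#' @param fov_mm transverse field of view (mm), square.
#' @param n_fast A-scans per B-scan.
#' @param n_bscans B-scans per volume.
#' @param ascan_rate_hz A-scan (depth profile) rate in Hz.
#' @param vol_duration_s duration of one volume raster including flyback (s).
#' @param gap_s inter-volume gap (s).
#' @param n_volumes number of consecutively acquired volumes.
#' @param first_fast fast axis of the first volume, `"x"` or `"y"`.
#' @return an `acquisition_protocol` object (list) with the derived
#'   transverse spacing in `spacing_um` and the alternating direction
#'   sequence in `directions`.
#' @examples
#' p <- acquisition_protocol()
#' p$spacing_um   # 12
#' p$total_s      # 14.6
#' @export
acquisition_protocol <- function(fov_mm = 6, n_fast = 500L, n_bscans = 500L,
                                 ascan_rate_hz = 128e3, vol_duration_s = 2.4,
                                 gap_s = 0.04, n_volumes = 6L,
                                 first_fast = c("x", "y")) {
  first_fast <- match.arg(first_fast)
  stopifnot(n_volumes >= 1, fov_mm > 0, n_fast >= 2, n_bscans >= 2,
            ascan_rate_hz > 0, vol_duration_s > 0, gap_s >= 0)
  dirs <- rep(if (first_fast == "x") c("x", "y") else c("y", "x"),
              length.out = n_volumes)
  structure(list(
    fov_mm = fov_mm, n_fast = as.integer(n_fast), n_bscans = as.integer(n_bscans),
    ascan_rate_hz = ascan_rate_hz, vol_duration_s = vol_duration_s,
    gap_s = gap_s, n_volumes = as.integer(n_volumes), directions = dirs,
    spacing_um = fov_mm * 1000 / n_fast,
    bscan_period_s = vol_duration_s / n_bscans,
    total_s = n_volumes * vol_duration_s + (n_volumes - 1) * gap_s
  ), class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %g x %g mm, %d x %d A-scans (%.3g um)\n",
              x$fov_mm, x$fov_mm, x$n_fast, x$n_bscans, x$spacing_um))
  cat(sprintf("  %d volumes (%s), %.3g s each + %.3g s gap = %.4g s total\n",
              x$n_volumes, paste(x$directions, collapse = ","),
              x$vol_duration_s, x$gap_s, x$total_s))
  invisible(x)
}

#' Start time of a volume within the acquisition
#' @param protocol an [acquisition_protocol()].
#' @param volume 1-based volume index.
#' @return start time in seconds.
#' @export
volume_start <- function(protocol, volume) {
  (volume - 1) * (protocol$vol_duration_s + protocol$gap_s)
}

#' Per-A-scan acquisition times of one volume
#'
#' @param protocol an [acquisition_protocol()].
#' @param volume 1-based volume index.
#' @return an `n_fast x n_bscans` matrix of times (s); column j holds the
#'   A-scan times of B-scan j.
#' @export
ascan_times <- function(protocol, volume = 1L) {
  t0 <- volume_start(protocol, volume)
  within <- (seq_len(protocol$n_fast) - 1) / protocol$ascan_rate_hz
  starts <- t0 + (seq_len(protocol$n_bscans) - 1) * protocol$bscan_period_s
  outer(within, starts, `+`)
}
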