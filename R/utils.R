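`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages in summary tables are rounded half-up (0.05 -> 0.1), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector (non-negative in intended use).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic child seed derived from a master seed and a label,
# kept within the 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# block-mean downsample a (nz, nx, ny) grid along z and x by integer factors
downsample_grid <- function(grid, fz = 1L, fx = 1L) {
  d <- dim(grid)
  if (fz == 1L && fx == 1L) return(grid)
  nz <- d[1] %/% fz; nx <- d[2] %/% fx
  g <- grid[seq_len(nz * fz), seq_len(nx * fx), , drop = FALSE]
  if (fz > 1L) {
    dim(g) <- c(fz, nz, nx * fx * d[3])
    g <- colMeans(g)
    dim(g) <- c(nz, nx * fx, d[3])
  }
  if (fx > 1L) {
    g <- aperm(g, c(2, 1, 3))
    dim(g) <- c(fx, nx, nz * d[3])
    g <- colMeans(g)
    dim(g) <- c(nx, nz, d[3])
    g <- aperm(g, c(2, 1, 3))
  }
  g
}

# nearest-valid hole filling for a 2D map with NA holes, by iterative
# neighbour averaging (valid cells keep their value)
fill_holes <- function(m) {
  if (!anyNA(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(nr + nc)) {
    holes <- which(is.na(m))
    if (!length(holes)) break
    pad <- matrix(NA_real_, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- m
    nb <- array(NA_real_, c(nr, nc, 4))
    nb[, , 1] <- pad[1:nr, 2:(nc + 1)]
    nb[, , 2] <- pad[3:(nr + 2), 2:(nc + 1)]
    nb[, , 3] <- pad[2:(nr + 1), 1:nc]
    nb[, , 4] <- pad[2:(nr + 1), 3:(nc + 2)]
    mean_nb <- apply(nb, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    m[holes] <- mean_nb[holes]
  }
  m
}

# running median with window k (odd), edges handled by shrinking window
run_med <- function(x, k = 3L) {
  n <- length(x)
  if (n < 3L || k < 3L) return(x)
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    median(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

# smooth random field on an nx x ny grid: white noise convolved with a
# Gaussian of correlation length corr_um, rescaled to unit sd
smooth_field <- function(nx, ny, pitch_um, corr_um) {
  sig <- max(corr_um / pitch_um, 1e-6)
  w <- matrix(rnorm(nx * ny), nx, ny)
  # spectral Gaussian smoothing on the torus (robust for any sigma)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  g <- outer(exp(-2 * (pi * sig * fx)^2), exp(-2 * (pi * sig * fy)^2))
  sm <- Re(fft(fft(w) * g, inverse = TRUE)) / (nx * ny)
  sm <- sm - mean(sm)
  s <- sd(sm)
  if (s < 1e-12) matrix(0, nx, ny) else sm / s
}

# quadratic (parabolic) sub-sample refinement around the minimum of a
# 1D sampled function; returns offset in [-0.5, 0.5]
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den <= 1e-12) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}
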