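#' Configuration of a synthetic retinal phantom
#'
#' The phantom is a layered reflectivity grid emulating a macular OCT cube:
#' four Gaussian bands (ILM, IS/OS ellipsoid zone, RPE, Bruch's membrane)
#' riding on a shared smooth undulation, diffuse inner-retina and choroid
#' fill, optional soft drusen (dome-shaped RPE elevations with BrM
#' unchanged) and dot-form subretinal drusenoid deposits (SDDs):
#' hyperreflective balls resting on the RPE. Stage-1 SDDs leave the IS/OS
#' untouched; stage-2 deposits locally elevate the IS/OS; stage-3 deposits
#' additionally reduce IS/OS reflectivity above the deposit.
#'
#' Depths are in micrometres from the top (anterior edge) of the grid; z
#' increases posteriorly. A multiplicative smooth reflectivity texture
#' emulates the en face granularity of real retinal tissue (and gives the
#' transverse image structure that motion estimation relies on).
#'
#' @param nx,ny,nz voxel counts (x fast-compatible, y, depth).
#' @param dxy_um transverse voxel spacing (um); 12 um matches the
#'   acquisition protocol.
#' @param dz_um axial voxel spacing (um); the default 2 um samples finer
#'   than the 2.7 um axial resolution of the instrument emulated.
#' @param depths_um named vector of mean layer depths (um) for
#'   `ilm`, `isos`, `rpe`, `brm`; must be strictly increasing.
#' @param refl named vector of band peak reflectivities (same names).
#' @param band_sigma_um named vector of band thickness sigmas (um).
#' @param undulation_um amplitude (sd, um) of the shared surface undulation.
#' @param undulation_corr_um correlation length of the undulation (um).
#' @param texture_amp relative sd of the multiplicative reflectivity
#'   texture (0 disables).
#' @param texture_corr_um correlation length of the texture (um).
#' @param background background reflectivity.
#' @param n_vessels number of inner-retinal vessels; their shadows give en
#'   face OCT its characteristic dark network (0 disables).
#' @param vessel_shadow fractional attenuation of signal beneath a vessel.
#' @param drusen data frame with columns `x_um, y_um, r_um, h_um` (druse
#'   centre, radius and apex height), or `NULL`.
#' @param sdds data frame with columns `x_um, y_um, r_um, stage`
#'   (stage in 1:3), or `NULL`.
#' @param sdd_refl reflectivity added inside an SDD deposit.
#' @param seed random seed used for undulation and texture.
#' @return a `phantom_config` object.
#' @export
phantom_config <- function(nx = 200L, ny = 200L, nz = 256L,
                           dxy_um = 12, dz_um = 2,
                           depths_um = c(ilm = 120, isos = 330, rpe = 362, brm = 382),
                           refl = c(ilm = 0.5, isos = 0.85, rpe = 1.0, brm = 0.55),
                           band_sigma_um = c(ilm = 5, isos = 6, rpe = 9, brm = 5),
                           undulation_um = 25, undulation_corr_um = 600,
                           texture_amp = 0.2, texture_corr_um = 120,
                           background = 0.04,
                           n_vessels = 18L, vessel_shadow = 0.45,
                           drusen = NULL, sdds = NULL, sdd_refl = 0.9,
                           seed = 1L) {
  nm <- c("ilm", "isos", "rpe", "brm")
  stopifnot(nx >= 4, ny >= 4, nz >= 8, dxy_um > 0, dz_um > 0,
            all(nm %in% names(depths_um)), all(nm %in% names(refl)),
            all(nm %in% names(band_sigma_um)))
  d <- depths_um[nm]
  if (any(diff(d) <= 0))
    stopf("layer depths must be strictly ordered ILM < IS/OS < RPE < BrM")
  if (!is.null(sdds)) {
    sdds <- as_tibble(sdds)
    stopifnot(all(c("x_um", "y_um", "r_um", "stage") %in% names(sdds)))
    if (!all(sdds$stage %in% 1:3)) stopf("SDD stage must be 1, 2 or 3")
    if (!all(sdds$r_um > 0)) stopf("SDD radius must be positive")
  }
  if (!is.null(drusen)) {
    drusen <- as_tibble(drusen)
    stopifnot(all(c("x_um", "y_um", "r_um", "h_um") %in% names(drusen)))
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dxy_um = dxy_um, dz_um = dz_um, depths_um = d,
                 refl = refl[nm], band_sigma_um = band_sigma_um[nm],
                 undulation_um = undulation_um,
                 undulation_corr_um = undulation_corr_um,
                 texture_amp = texture_amp, texture_corr_um = texture_corr_um,
                 background = background, n_vessels = as.integer(n_vessels),
                 vessel_shadow = vessel_shadow,
                 drusen = drusen, sdds = sdds,
                 sdd_refl = sdd_refl, seed = as.integer(seed)),
            class = "phantom_config")
}

# dome profile: height h at centre, 0 at radius r
dome <- function(rho, r, h) h * pmax(0, 1 - (rho / r)^2)

# transverse vessel-shadow map: random smooth vessel paths rasterized and
# blurred; values in (0, 1], 1 = unshadowed
vessel_shadow_map <- function(nx, ny, pitch_um, n_vessels, strength) {
  if (n_vessels < 1 || strength <= 0) return(matrix(1, nx, ny))
  acc <- matrix(0, nx, ny)
  for (v in seq_len(n_vessels)) {
    # start on a random edge, walk across with curvature noise
    edge <- sample(4, 1)
    pos <- switch(edge,
                  c(1, runif(1, 1, ny)), c(nx, runif(1, 1, ny)),
                  c(runif(1, 1, nx), 1), c(runif(1, 1, nx), ny))
    ang <- atan2(ny / 2 - pos[2], nx / 2 - pos[1]) + rnorm(1, 0, 0.5)
    amp <- runif(1, 0.6, 1)
    nstep <- 3L * (nx + ny)
    for (s in seq_len(nstep)) {
      ix <- round(pos[1]); iy <- round(pos[2])
      if (ix < 1 || ix > nx || iy < 1 || iy > ny) break
      acc[ix, iy] <- acc[ix, iy] + amp
      ang <- ang + rnorm(1, 0, 0.15)
      pos <- pos + 0.7 * c(cos(ang), sin(ang))
    }
  }
  sig <- max(18 / pitch_um, 0.8)  # ~vessel calibre
  acc <- EBImage::imageData(EBImage::gblur(acc, sigma = sig))
  1 - strength * tanh(2.5 * acc)
}

#' Render a phantom from its configuration
#'
#' Builds the reflectivity grid and the ground-truth surfaces and SDD list
#' used as oracles by the downstream processing tests.
#'
#' @param cfg a [phantom_config()].
#' @return a `phantom` object: `grid` (nz x nx x ny reflectivity array),
#'   `surfaces` (list of nx x ny depth maps in um: `ilm`, `isos`, `rpe`,
#'   `prpe`, `brm`), `sdds` (ground-truth tibble with voxel counts), and
#'   the configuration.
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz
  und <- if (cfg$undulation_um > 0) {
    f <- smooth_field(nx, ny, cfg$dxy_um, cfg$undulation_corr_um)
    cfg$undulation_um * f / max(abs(f))  # amplitude = peak deviation
  } else matrix(0, nx, ny)
  tex <- if (cfg$texture_amp > 0) {
    matrix(pmax(1 + cfg$texture_amp * smooth_field(nx, ny, cfg$dxy_um, cfg$texture_corr_um),
                0.2), nx, ny)
  } else matrix(1, nx, ny)

  shadow <- vessel_shadow_map(nx, ny, cfg$dxy_um, cfg$n_vessels,
                              cfg$vessel_shadow)

  d <- cfg$depths_um
  ilm <- d[["ilm"]] + und; isos <- d[["isos"]] + und
  rpe <- d[["rpe"]] + und; brm <- d[["brm"]] + und

  xs_um <- (seq_len(nx) - 1) * cfg$dxy_um
  ys_um <- (seq_len(ny) - 1) * cfg$dxy_um

  # soft drusen: dome elevation of RPE (and IS/OS riding on it); BrM fixed
  druse_fill_top <- matrix(Inf, nx, ny)
  if (!is.null(cfg$drusen) && nrow(cfg$drusen)) {
    for (k in seq_len(nrow(cfg$drusen))) {
      dk <- cfg$drusen[k, ]
      rho <- sqrt(outer((xs_um - dk$x_um)^2, (ys_um - dk$y_um)^2, `+`))
      e <- dome(rho, dk$r_um, dk$h_um)
      rpe <- rpe - e
      isos <- isos - e
      ilm <- ilm - 0.3 * e  # inner retina drapes mildly over large drusen
    }
    druse_fill_top <- rpe + 2 * cfg$band_sigma_um[["rpe"]]
  }

  # SDDs: ball tangent on the RPE, anterior side
  sdd_tab <- cfg$sdds
  sdd_mat <- matrix(numeric(0), 0, 5)
  isos_scale <- matrix(1, nx, ny)
  if (!is.null(sdd_tab) && nrow(sdd_tab)) {
    sdd_mat <- matrix(0, nrow(sdd_tab), 5)
    for (k in seq_len(nrow(sdd_tab))) {
      sk <- sdd_tab[k, ]
      cx <- sk$x_um / cfg$dxy_um; cy <- sk$y_um / cfg$dxy_um
      ix <- pmin(pmax(round(cx) + 1, 1), nx); iy <- pmin(pmax(round(cy) + 1, 1), ny)
      cz <- rpe[ix, iy] - cfg$band_sigma_um[["rpe"]] - sk$r_um
      sdd_mat[k, ] <- c(cx, cy, cz, sk$r_um, cfg$sdd_refl)
      if (sk$stage >= 2) {
        rho <- sqrt(outer((xs_um - sk$x_um)^2, (ys_um - sk$y_um)^2, `+`))
        gap <- isos[ix, iy] - ilm[ix, iy]
        lift <- min(2 * sk$r_um, 0.5 * gap)
        isos <- isos - dome(rho, 1.6 * sk$r_um, lift)
      }
      if (sk$stage >= 3) {
        rho <- sqrt(outer((xs_um - sk$x_um)^2, (ys_um - sk$y_um)^2, `+`))
        isos_scale <- isos_scale * (1 - 0.6 * (rho <= 1.6 * sk$r_um))
      }
    }
  }

  margin <- 2 * max(cfg$band_sigma_um)
  if (any(isos - ilm <= margin) || any(rpe - isos <= 0) || any(brm - rpe <= 0) ||
      any(ilm < 4 * cfg$band_sigma_um[["ilm"]]) ||
      any(brm > (nz - 1) * cfg$dz_um - 4 * cfg$band_sigma_um[["brm"]]))
    stopf("layer ordering violated after undulation/drusen insertion; adjust the configuration")

  # vessel shadows attenuate everything posterior to the inner retina
  outer_tex <- tex * shadow
  fills_top <- list(ilm + 10, brm + 8)
  fills_bot <- list(isos - 15, matrix((nz - 1) * cfg$dz_um, nx, ny))
  fills_refl <- c(0.16, 0.12)
  fills_scale <- list(tex, outer_tex)
  if (is.finite(druse_fill_top[1, 1]) || any(is.finite(druse_fill_top))) {
    fills_top <- c(fills_top, list(druse_fill_top))
    fills_bot <- c(fills_bot, list(brm - 2 * cfg$band_sigma_um[["brm"]]))
    fills_refl <- c(fills_refl, 0.3)
    fills_scale <- c(fills_scale, list(tex))
  }

  rend <- render_phantom_cpp(
    nz, cfg$dz_um, cfg$dxy_um,
    layer_depth = list(ilm, isos, rpe, brm),
    layer_refl = as.numeric(cfg$refl),
    layer_sigma = as.numeric(cfg$band_sigma_um),
    layer_scale = list(tex, outer_tex * isos_scale, outer_tex, outer_tex),
    background = cfg$background,
    fill_top = fills_top, fill_bot = fills_bot,
    fill_refl = fills_refl, fill_scale = fills_scale,
    sdd = sdd_mat)

  gt_sdds <- if (!is.null(sdd_tab) && nrow(sdd_tab)) {
    dplyr::mutate(sdd_tab, id = dplyr::row_number(),
                  n_voxels = as.integer(rend$sdd_voxels))
  } else {
    tibble(x_um = numeric(), y_um = numeric(), r_um = numeric(),
           stage = integer(), id = integer(), n_voxels = integer())
  }

  structure(list(
    grid = rend$grid,
    surfaces = list(ilm = ilm, isos = isos, rpe = rpe,
                    prpe = rpe + cfg$band_sigma_um[["rpe"]], brm = brm),
    sdds = gt_sdds, cfg = cfg
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<phantom> %d x %d x %d voxels (%g um transverse, %g um axial)\n",
              d[2], d[3], d[1], x$cfg$dxy_um, x$cfg$dz_um))
  cat(sprintf("  BrM mean depth %.1f um; %d drusen; %d SDDs\n",
              mean(x$surfaces$brm),
              if (is.null(x$cfg$drusen)) 0L else nrow(x$cfg$drusen),
              nrow(x$sdds)))
  invisible(x)
}
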