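SIDECAR_SCHEMA <- 1L

#' Write a raster volume to disk
#'
#' The grid is stored as NIfTI (double precision, bit-exact round trip)
#' and the acquisition metadata as a JSON sidecar next to it
#' (`<stem>.json`). Per-A-scan times are reconstructed from the protocol
#' timing model on read.
#'
#' @param volume a `raster_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return invisibly, the sidecar path.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "raster_volume"))
  RNifti::writeNifti(volume$grid, path, datatype = "double")
  side <- list(
    schema = SIDECAR_SCHEMA,
    protocol = unclass(volume$protocol)[c("fov_mm", "n_fast", "n_bscans",
                                          "ascan_rate_hz", "vol_duration_s",
                                          "gap_s", "n_volumes")],
    first_fast = volume$protocol$directions[1],
    direction = volume$direction,
    index = volume$index,
    dims = dim(volume$grid),
    mask = volume$mask,
    blinks_gt = volume$meta$blinks_gt,
    blink_floor = volume$meta$blink_floor,
    seed = volume$meta$seed,
    phantom_dxy_um = volume$meta$phantom_dxy_um,
    phantom_dz_um = volume$meta$phantom_dz_um
  )
  sp <- sidecar_path(path)
  jsonlite::write_json(side, sp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sp)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a raster volume written by [write_volume()]
#'
#' @param path the NIfTI path.
#' @param sidecar the JSON sidecar path; defaults to `<stem>.json`.
#' @return a `raster_volume`.
#' @export
read_volume <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$schema) || side$schema > SIDECAR_SCHEMA)
    stopf("unsupported sidecar schema version: %s", side$schema %||% "missing")
  nii <- RNifti::readNifti(path)
  grid <- array(as.numeric(nii), dim = dim(nii))
  if (!identical(as.integer(dim(grid)), as.integer(side$dims)))
    stopf("dimension mismatch: grid is %s but sidecar declares %s",
          paste(dim(grid), collapse = " x "), paste(side$dims, collapse = " x "))
  p <- side$protocol
  protocol <- acquisition_protocol(fov_mm = p$fov_mm, n_fast = p$n_fast,
                                   n_bscans = p$n_bscans,
                                   ascan_rate_hz = p$ascan_rate_hz,
                                   vol_duration_s = p$vol_duration_s,
                                   gap_s = p$gap_s, n_volumes = p$n_volumes,
                                   first_fast = side$first_fast)
  if (dim(grid)[2] != protocol$n_fast || dim(grid)[3] != protocol$n_bscans)
    stopf("dimension mismatch: grid is %s but protocol declares nz x %d x %d",
          paste(dim(grid), collapse = " x "), protocol$n_fast, protocol$n_bscans)
  vol <- new_raster_volume(grid, protocol, side$direction, side$index,
                           meta = list(blinks_gt = side$blinks_gt,
                                       blink_floor = side$blink_floor,
                                       seed = side$seed,
                                       phantom_dxy_um = side$phantom_dxy_um,
                                       phantom_dz_um = side$phantom_dz_um))
  vol$mask <- as.logical(side$mask)
  vol
}

#' Detect blink-corrupted B-scans by relative thresholding
#'
#' A B-scan is flagged as a blink when its mean intensity falls below
#' `rel_threshold` times the median of all B-scan means. The criterion is
#' relative, so detection is invariant to global intensity scaling.
#'
#' @param volume a `raster_volume`.
#' @param rel_threshold fraction of the median B-scan mean (0 < t < 1).
#' @param dark_floor absolute mean intensity below which the whole volume
#'   is considered signal-free (guards the relative criterion when most
#'   B-scans are dark).
#' @return integer vector of flagged B-scan indices (1-based).
#' @export
detect_blinks <- function(volume, rel_threshold = 0.3, dark_floor = 0.02) {
  stopifnot(inherits(volume, "raster_volume"),
            rel_threshold > 0, rel_threshold < 1)
  means <- apply(volume$grid, 3, mean)
  if (median(means) <= dark_floor)
    stopf("volume unusable: median B-scan intensity at the noise floor")
  flagged <- which(means < rel_threshold * median(means))
  if (length(flagged) > 0.5 * length(means))
    stopf("volume unusable: %d of %d B-scans flagged as blinks",
          length(flagged), length(means))
  flagged
}

#' Mask B-scans out of downstream processing
#'
#' Masked B-scans are retained in the data (preserving timing continuity)
#' but excluded from motion, illumination, surface and fusion estimation.
#'
#' @param volume a `raster_volume`.
#' @param indices B-scan indices to mask.
#' @return the volume with an updated validity mask.
#' @export
mask_blinks <- function(volume, indices) {
  stopifnot(inherits(volume, "raster_volume"))
  volume$mask[indices] <- FALSE
  volume
}

#' Detect and mask blinks in one step
#' @inheritParams detect_blinks
#' @return the volume with blink B-scans masked.
#' @export
remove_blinks <- function(volume, rel_threshold = 0.3) {
  mask_blinks(volume, detect_blinks(volume, rel_threshold))
}

#' Write a 2D map (en face slab or surface depth map) as TIFF + JSON
#'
#' Values are scaled into `[0, 1]` for 32-bit float TIFF storage; the scale
#' and offset are recorded in the JSON sidecar so [read_map()] restores the
#' original values.
#'
#' @param m numeric matrix.
#' @param path output `.tif` path.
#' @param meta extra metadata stored in the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_map <- function(m, path, meta = list()) {
  rng <- range(m, finite = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  m01 <- (m - rng[1]) / scale
  m01[!is.finite(m01)] <- 0
  tiff::writeTIFF(t(m01), path, bits.per.sample = 32L)
  side <- c(list(schema = SIDECAR_SCHEMA, offset = rng[1], scale = scale,
                 dims = dim(m)), meta)
  sp <- paste0(sub("\\.tiff?$", "", path), ".json")
  jsonlite::write_json(side, sp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sp)
}

#' Read a map written by [write_map()]
#' @param path the `.tif` path.
#' @return numeric matrix with a `meta` attribute.
#' @export
read_map <- function(path) {
  sp <- paste0(sub("\\.tiff?$", "", path), ".json")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  m <- t(tiff::readTIFF(path)) * side$scale + side$offset
  attr(m, "meta") <- side
  m
}

# ---- ground-truth serialization ----------------------------------------
# Simulation ground truth (traces, surfaces, SDD tables, bias fields,
# blink ranges) must survive a write/read cycle bit-exactly so tests can
# rely on it; doubles are therefore serialized as full-precision "%.17g"
# strings rather than JSON numbers.

encode_gt <- function(x) {
  if (is.data.frame(x)) {
    list(.t = "df", cols = lapply(as.list(x), encode_gt))
  } else if (is.double(x)) {
    list(.t = "dbl", dim = dim(x), v = sprintf("%.17g", as.numeric(x)))
  } else if (is.integer(x)) {
    list(.t = "int", dim = dim(x), v = x)
  } else if (is.character(x) || is.logical(x) || is.null(x)) {
    list(.t = "raw", v = x)
  } else if (is.list(x)) {
    list(.t = "list", names = names(x), items = lapply(unname(x), encode_gt))
  } else {
    list(.t = "raw", v = x)
  }
}

decode_gt <- function(e) {
  switch(unlist(e$.t),
    df = as_tibble(lapply(e$cols, decode_gt)),
    dbl = {
      v <- as.numeric(unlist(e$v))
      if (length(e$dim)) dim(v) <- unlist(e$dim)
      v
    },
    int = {
      v <- as.integer(unlist(e$v))
      if (length(e$dim)) dim(v) <- unlist(e$dim)
      v
    },
    raw = if (is.null(e$v)) NULL else unlist(e$v),
    list = {
      out <- lapply(e$items, decode_gt)
      if (!is.null(e$names)) names(out) <- unlist(e$names)
      out
    })
}

#' Write simulation ground truth as JSON (bit-exact round trip)
#'
#' Stores nested lists of numeric arrays, data frames and metadata (motion
#' traces, layer surfaces, SDD tables, bias fields, blink ranges) with
#' full-precision encoding so [read_ground_truth()] reproduces every
#' double bit for bit.
#'
#' @param gt a (possibly nested) list of numeric arrays, data frames and
#'   atomic vectors.
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(encode_gt(gt), path, auto_unbox = FALSE,
                       null = "null")
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path the `.json` path.
#' @return the restored object.
#' @export
read_ground_truth <- function(path) {
  decode_gt(jsonlite::read_json(path, simplifyVector = FALSE))
}
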