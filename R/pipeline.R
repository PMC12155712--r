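#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults,
#' including the acquisition protocol (12 um spacing), the slab definition
#' (27-77 um above BrM) and the tracking match radius. Any subset can be
#' overridden in the YAML/list passed to [run_pipeline()]; unknown keys
#' are rejected.
#'
#' @return a nested list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(blinks = TRUE, motion = TRUE, illum = TRUE,
                  fuse = TRUE, enface = TRUE, track = FALSE),
    phantom = list(nx = 200L, ny = 200L, nz = 256L, dxy_um = 12, dz_um = 2,
                   undulation_um = 25, texture_amp = 0.2,
                   sdds = NULL, drusen = NULL),
    protocol = list(fov_mm = NULL, n_fast = NULL, n_bscans = NULL,
                    vol_duration_s = 2.4, gap_s = 0.04, n_volumes = 4L),
    motion_sim = list(drift_sd_um_rts = 10, axial_sd_um_rts = 2,
                      saccade_rate_hz = 0, saccade_amp_um = 60),
    noise = list(speckle_contrast = 0.35, detector_sd = 0.01,
                 bias_amplitude = 0),
    blinks = list(rel_threshold = 0.3, inject = NULL),
    motion = list(levels = c(4L, 2L, 1L), sweeps = c(2L, 1L, 2L)),
    illum = list(n_ctrl = 8L),
    fuse = list(target_frac = 0.75),
    enface = list(reference = "brm", lower_um = 27, upper_um = 77),
    track = list(follow_sdds = NULL, shift_um = c(0, 0),
                 match_radius_um = 60, laterality = "OD", fovea = NULL,
                 contrast_min = 0.15)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stopf("unknown configuration key: %s", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.data.frame(defaults[[key]]) && !is.data.frame(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the full synthetic pipeline from one configuration
#'
#' Simulates the configured multi-volume acquisition(s), removes blinks,
#' estimates and applies motion and illumination corrections, fuses and
#' flattens to BrM, generates the en face slab, and (optionally) simulates
#' a follow-up visit and tracks SDD changes. All randomness derives from
#' the single configured seed, so reruns with the same configuration are
#' bit-reproducible.
#'
#' @param config a nested list, or path to a YAML file, overriding
#'   [default_pipeline_config()]; unknown keys raise a validation error
#'   naming the key. `out_dir` must be set.
#' @return a run manifest: tibble of artifacts with MD5 content hashes,
#'   stage timings, and the effective configuration.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$out_dir)) stopf("config must set out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  artifacts <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  add_artifact <- function(name, path) {
    artifacts[[length(artifacts) + 1]] <<- tibble(
      name = name, path = path, md5 = unname(tools::md5sum(path)))
  }

  pc <- cfg$protocol
  protocol <- acquisition_protocol(
    fov_mm = pc$fov_mm %||% (cfg$phantom$nx * cfg$phantom$dxy_um / 1000),
    n_fast = pc$n_fast %||% cfg$phantom$nx,
    n_bscans = pc$n_bscans %||% cfg$phantom$ny,
    vol_duration_s = pc$vol_duration_s, gap_s = pc$gap_s,
    n_volumes = pc$n_volumes)

  process_visit <- function(visit, sdds, origin_um) {
    ph_args <- cfg$phantom
    ph_args$sdds <- sdds
    ph_args$seed <- derive_seed(cfg$seed, "phantom")
    phantom <- tick(paste0("phantom_", visit),
                    do.call(phantom_config, ph_args) |> make_phantom())
    mp <- motion_params(drift_sd_um_rts = cfg$motion_sim$drift_sd_um_rts,
                        axial_sd_um_rts = cfg$motion_sim$axial_sd_um_rts,
                        saccade_rate_hz = cfg$motion_sim$saccade_rate_hz,
                        saccade_amp_um = cfg$motion_sim$saccade_amp_um)
    traces <- lapply(seq_len(protocol$n_volumes), function(v)
      simulate_motion(protocol$vol_duration_s, mp,
                      seed = derive_seed(cfg$seed, paste0(visit, "_trace", v))))
    bias <- if (cfg$noise$bias_amplitude > 0) {
      make_bias(protocol, cfg$noise$bias_amplitude,
                seed = derive_seed(cfg$seed, paste0(visit, "_bias")))
    } else NULL
    vols <- tick(paste0("acquire_", visit),
                 acquire(phantom, protocol, traces, bias = bias,
                         speckle_contrast = cfg$noise$speckle_contrast,
                         detector_sd = cfg$noise$detector_sd,
                         seed = derive_seed(cfg$seed, paste0(visit, "_noise")),
                         origin_um = origin_um))
    if (!is.null(cfg$blinks$inject)) {
      vols[[1]] <- inject_blinks(vols[[1]], cfg$blinks$inject)
    }
    if (isTRUE(cfg$stages$blinks)) {
      vols <- tick(paste0("blinks_", visit),
                   lapply(vols, remove_blinks,
                          rel_threshold = cfg$blinks$rel_threshold))
    }
    model <- if (isTRUE(cfg$stages$motion)) {
      tick(paste0("motion_", visit),
           estimate_motion(vols, motion_opts(levels = cfg$motion$levels,
                                             sweeps = cfg$motion$sweeps)))
    } else NULL
    samples <- lapply(vols, correct_volume, model = model)
    if (isTRUE(cfg$stages$illum)) {
      gain <- tick(paste0("illum_", visit),
                   estimate_gain(samples, n_ctrl = cfg$illum$n_ctrl))
      gain <- set_brightness_scales(gain, match_brightness(samples))
      samples <- lapply(samples, apply_gain, gain = gain)
    }
    fused <- tick(paste0("fuse_", visit), {
      surfs <- lapply(vols, segment_surface, layer = cfg$enface$reference)
      ref <- mean_surface(surfs, model)
      flatten_and_merge(samples, ref, target_frac = cfg$fuse$target_frac)
    })
    slab <- make_slab(fused, slab_spec(cfg$enface$reference,
                                       cfg$enface$lower_um,
                                       cfg$enface$upper_um), visit = visit)
    sp <- file.path(cfg$out_dir, paste0("slab_", visit, ".tif"))
    write_map(slab$img, sp, meta = list(visit = visit,
                                        pitch_um = slab$pitch_um,
                                        lower_um = cfg$enface$lower_um,
                                        upper_um = cfg$enface$upper_um,
                                        reference = cfg$enface$reference,
                                        seed = cfg$seed))
    add_artifact(paste0("slab_", visit), sp)
    slab
  }

  slab_base <- process_visit("baseline", cfg$phantom$sdds, c(0, 0))

  if (isTRUE(cfg$stages$track)) {
    slab_follow <- process_visit("followup", cfg$track$follow_sdds,
                                 cfg$track$shift_um)
    tf <- register_visits(slab_base, slab_follow)
    det_b <- detect_sdd(slab_base, contrast_min = cfg$track$contrast_min)
    det_f <- detect_sdd(slab_follow, contrast_min = cfg$track$contrast_min)
    rec <- classify_changes(det_b, det_f, tf,
                            radius_um = cfg$track$match_radius_um)
    fov <- cfg$track$fovea %||%
      (c(nrow(slab_base$img), ncol(slab_base$img)) - 1) / 2 * slab_base$pitch_um
    rec <- add_quadrants(rec, fov, cfg$track$laterality)
    summ <- summarize_changes(rec)
    rp <- file.path(cfg$out_dir, "change_records.csv")
    write.csv(rec, rp, row.names = FALSE)
    add_artifact("change_records", rp)
    sp2 <- file.path(cfg$out_dir, "summary.csv")
    write.csv(tidy(summ), sp2, row.names = FALSE)
    add_artifact("summary", sp2)
  }

  mp <- file.path(cfg$out_dir, "manifest.json")
  manifest <- list(
    artifacts = dplyr::bind_rows(artifacts),
    timings = tibble(stage = names(timings),
                     seconds = as.numeric(unlist(timings))),
    config = cfg, seed = cfg$seed)
  jsonlite::write_json(list(artifacts = manifest$artifacts,
                            timings = manifest$timings, seed = cfg$seed),
                       mp, auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
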