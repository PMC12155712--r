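# Shared small fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# small square protocol matched to an n x n phantom at 12 um pitch
small_protocol <- function(n, n_volumes = 2L, vol_duration_s = 0.5) {
  acquisition_protocol(fov_mm = n * 12 / 1000, n_fast = n, n_bscans = n,
                       n_volumes = n_volumes, vol_duration_s = vol_duration_s)
}

# flat, noiseless phantom: parallel layers, no texture, no vessels
flat_phantom <- function(n = 40) {
  memo(paste0("flat", n), make_phantom(phantom_config(
    nx = n, ny = n, nz = 224, undulation_um = 0, texture_amp = 0,
    n_vessels = 0L)))
}

# default-realism phantom (undulation, texture, vessels)
textured_phantom <- function(n = 80, und = 25) {
  memo(paste0("tex", n, "_", und), make_phantom(phantom_config(
    nx = n, ny = n, nz = 224, undulation_um = und)))
}

# noiseless static acquisition of a phantom
clean_volumes <- function(phantom, n_volumes = 2L) {
  n <- phantom$cfg$nx
  acquire(phantom, small_protocol(n, n_volumes), traces = NULL,
          speckle_contrast = 0, detector_sd = 0)
}

# synthetic en face slab with Gaussian dot deposits at given centres
blob_slab <- function(centers, n = 160, pitch = 12, amp = 0.5, bg = 0.3,
                      texture = 0.05, seed = 1, visit = NA_character_) {
  set.seed(seed)
  img <- matrix(bg, n, n) + if (texture > 0) {
    texture * smooth_field_test(n, pitch, 200)
  } else 0
  xs <- (seq_len(n) - 1) * pitch
  for (k in seq_len(nrow(centers))) {
    r <- if ("r_um" %in% names(centers)) centers$r_um[k] else 45
    d2 <- outer((xs - centers$x_um[k])^2, (xs - centers$y_um[k])^2, `+`)
    img <- img + amp * exp(-d2 / (2 * (r / 1.6)^2))
  }
  structure(list(img = img, spec = slab_spec(), pitch_um = pitch,
                 visit = visit), class = "enface_slab")
}

# independent smooth random field for test fixtures (spectral method)
smooth_field_test <- function(n, pitch, corr_um) {
  sig <- corr_um / pitch
  w <- matrix(rnorm(n * n), n, n)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  g <- outer(exp(-2 * (pi * sig * f)^2), exp(-2 * (pi * sig * f)^2))
  sm <- Re(fft(fft(w) * g, inverse = TRUE)) / (n * n)
  sm <- sm - mean(sm)
  s <- sd(sm)
  if (s > 0) sm / s else sm
}

# random, well-separated dot centres inside the field
random_centers <- function(k, lo = 200, hi = 1700, min_sep = 160, seed = 1) {
  set.seed(seed)
  cents <- data.frame(x_um = runif(k, lo, hi), y_um = runif(k, lo, hi),
                      r_um = runif(k, 30, 60))
  repeat {
    d <- as.matrix(dist(cents[, 1:2])); diag(d) <- Inf
    if (min(d) >= min_sep) break
    i <- which(d == min(d), arr.ind = TRUE)[1, 1]
    cents[i, 1:2] <- runif(2, lo, hi)
  }
  cents
}

# gauge-aligned median 3D displacement error between a model and truth
motion_error <- function(model, traces, protocol) {
  est <- do.call(rbind, model$disp)
  tru <- do.call(rbind, lapply(seq_along(traces), function(v)
    eval_trace(traces[[v]], model$times[[v]] - volume_start(protocol, v))))
  d <- sweep(est, 2, colMeans(est)) - sweep(tru, 2, colMeans(tru))
  median(sqrt(rowSums(d^2)))
}

# brute-force change classification implementing the published rule with
# independent exhaustive loops (test oracle)
oracle_classify <- function(base, follow, radius) {
  nb <- nrow(base); nf <- nrow(follow)
  nearest <- integer(0)
  if (nb > 0) {
    nearest <- rep(NA_integer_, nb)
    for (i in seq_len(nb)) {
      best <- NA_integer_; bestd <- Inf
      for (j in seq_len(nf)) {
        dij <- sqrt((base$x_um[i] - follow$x_um[j])^2 +
                    (base$y_um[i] - follow$y_um[j])^2)
        if (dij < bestd) { bestd <- dij; best <- j }
      }
      if (!is.na(best) && bestd <= radius) nearest[i] <- best
    }
  }
  cats <- rep("regressed", nb)
  for (i in seq_len(nb)) {
    j <- nearest[i]
    if (is.na(j)) next
    sharers <- sum(!is.na(nearest) & nearest == j)
    if (sharers >= 2) { cats[i] <- "fused"; next }
    # mutual nearest neighbour
    bb <- NA_integer_; bd <- Inf
    for (i2 in seq_len(nb)) {
      d2 <- sqrt((base$x_um[i2] - follow$x_um[j])^2 +
                 (base$y_um[i2] - follow$y_um[j])^2)
      if (d2 < bd) { bd <- d2; bb <- i2 }
    }
    if (identical(bb, i) && bd <= radius) cats[i] <- "stable"
  }
  n_new <- 0
  for (j in seq_len(nf)) {
    if (!any(!is.na(nearest) & nearest == j)) n_new <- n_new + 1
  }
  list(base_categories = cats, n_new = n_new)
}

fuse_fixture <- function() {
  memo("fuse_fix", {
    ph <- textured_phantom(80, und = 25)
    proto <- small_protocol(80, 6L)
    vols <- acquire(ph, proto, NULL, speckle_contrast = 0.35,
                    detector_sd = 0.01, seed = 3)
    samples <- lapply(vols, correct_volume)
    surfs <- lapply(vols, segment_surface, layer = "brm")
    ref <- mean_surface(surfs, NULL)
    list(ph = ph, proto = proto, vols = vols, samples = samples,
         surfs = surfs, ref = ref,
         fused = flatten_and_merge(samples, ref))
  })
}


# add a deterministic instantaneous saccade to a motion trace
add_step_saccade <- function(trace, t_s, jump_um) {
  pre <- as.numeric(eval_trace(trace, t_s))
  after <- trace$t > t_s
  d <- trace$d
  d[after, ] <- sweep(d[after, , drop = FALSE], 2, jump_um, `+`)
  trace$d <- rbind(d[!after, , drop = FALSE], pre, pre + jump_um,
                   d[after, , drop = FALSE])
  trace$t <- c(trace$t[!after], t_s, t_s + 1e-9, trace$t[after])
  trace$saccade_times <- sort(c(trace$saccade_times, t_s))
  trace
}

# outer-retina en face projection of gridded corrected samples
enface_band <- function(samples, nz, n, dz_um, pitch_um, rows) {
  sc <- octfuse:::scatter_samples(list(samples), nz, n, n, dz_um, pitch_um)
  v <- octfuse:::value_grid(sc$sum, sc$wsum)
  apply(v[rows, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
}

# x-offset (in voxels) between two en face images via their row profiles
profile_xoff <- function(a, ref, range = 10) {
  pa <- rowMeans(a, na.rm = TRUE); pb <- rowMeans(ref, na.rm = TRUE)
  pa <- pa - mean(pa, na.rm = TRUE); pb <- pb - mean(pb, na.rm = TRUE)
  n <- length(pa)
  cc <- vapply(-range:range, function(s) {
    ia <- max(1, 1 + s):min(n, n + s)
    sum(pa[ia] * pb[ia - s], na.rm = TRUE) / length(ia)
  }, numeric(1))
  (-range:range)[which.max(cc)]
}

# en face discontinuity across a saccade B-scan: difference of split-half
# x-offsets against the motion-free reference
saccade_discontinuity <- function(ef, ef_ref, split) {
  o1 <- profile_xoff(ef[, 1:(split - 1)], ef_ref[, 1:(split - 1)])
  o2 <- profile_xoff(ef[, split:ncol(ef)], ef_ref[, split:ncol(ef)])
  abs(o2 - o1)
}

# full-pipeline longitudinal scenario: 6 stable, 2 regressed, 1 merged
# pair (2 fused members), 1 new, with a known inter-visit fixation shift
e2e_sdds <- function() {
  base <- data.frame(
    x_um = c(250, 420, 800, 1100, 950, 300, 640, 660, 1150, 420),
    y_um = c(300, 900, 280, 1100, 650, 1250, 515, 595, 820, 620),
    r_um = c(45, 50, 45, 55, 48, 52, 40, 40, 46, 44),
    stage = c(1, 2, 1, 3, 2, 1, 1, 1, 2, 1))
  follow <- rbind(
    base[1:6, ],
    data.frame(x_um = 650, y_um = 555, r_um = 60, stage = 2),
    data.frame(x_um = 1000, y_um = 1150, r_um = 48, stage = 2))
  list(base = base, follow = follow)
}

e2e_visit_slab <- function(sdds, origin_um, visit, seed) {
  n <- 120
  ph <- make_phantom(phantom_config(nx = n, ny = n, nz = 224,
                                    undulation_um = 20, sdds = sdds,
                                    seed = 2))
  proto <- small_protocol(n, 2L, vol_duration_s = 0.6)
  vols <- acquire(ph, proto, NULL, speckle_contrast = 0.35,
                  detector_sd = 0.01, seed = seed, origin_um = origin_um)
  samples <- lapply(vols, correct_volume)
  fused <- fuse_to_reference(vols, samples, NULL, "brm")
  make_slab(fused, visit = visit)
}

e2e_counts <- function(seed = 5) {
  sdds <- e2e_sdds()
  sb <- e2e_visit_slab(sdds$base, c(0, 0), "baseline", seed)
  sf <- e2e_visit_slab(sdds$follow, c(36, -24), "followup", seed + 1)
  tf <- register_visits(sb, sf)
  db <- detect_sdd(sb, contrast_min = 0.3)
  df <- detect_sdd(sf, contrast_min = 0.3)
  rec <- classify_changes(db, df, tf, 60)
  summarize_changes(rec)
}
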