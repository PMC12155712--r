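test_that("degenerate flat configuration renders parallel constant layers", {
  ph <- flat_phantom(40)
  expect_true(all(ph$grid >= 0))
  expect_equal(max(abs(ph$surfaces$brm - 382)), 0)
  expect_equal(max(abs(ph$surfaces$ilm - 120)), 0)
  # brightest voxel of a central column sits at the RPE depth
  col <- ph$grid[, 20, 20]
  expect_equal((which.max(col) - 1) * 2, 362, tolerance = 0.02)
})

test_that("layer ordering violations are rejected at render time", {
  cfg <- phantom_config(nx = 8, ny = 8, nz = 64, undulation_um = 0,
                        texture_amp = 0, n_vessels = 0L)
  # axial grid too shallow for the configured depths
  expect_error(make_phantom(cfg), "ordering")
  expect_error(phantom_config(depths_um = c(ilm = 300, isos = 200,
                                            rpe = 362, brm = 382)),
               "ordered")
})

test_that("stage-1 SDDs do not elevate the IS/OS surface; stages 2-3 do", {
  base <- make_phantom(phantom_config(nx = 60, ny = 60, nz = 224,
                                      undulation_um = 0, texture_amp = 0,
                                      n_vessels = 0L))
  for (stg in 1:3) {
    ph <- make_phantom(phantom_config(
      nx = 60, ny = 60, nz = 224, undulation_um = 0, texture_amp = 0,
      n_vessels = 0L,
      sdds = data.frame(x_um = 360, y_um = 360, r_um = 30, stage = stg)))
    expect_equal(nrow(ph$sdds), 1L)
    dev <- max(abs(ph$surfaces$isos - base$surfaces$isos))
    if (stg == 1) expect_equal(dev, 0) else expect_gt(dev, 10)
  }
})

test_that("inserted spherical deposits have near-analytic voxel volume", {
  # oracle: closed-form sphere volume / voxel volume; also an independent
  # brute-force voxel enumeration of the ball
  cfg <- phantom_config(nx = 80, ny = 80, nz = 224, undulation_um = 0,
                        texture_amp = 0, n_vessels = 0L,
                        sdds = data.frame(x_um = c(300, 600),
                                          y_um = c(300, 600),
                                          r_um = c(48, 60), stage = c(1, 1)))
  ph <- make_phantom(cfg)
  for (k in 1:2) {
    r <- cfg$sdds$r_um[k]
    analytic <- 4 / 3 * pi * r^3 / (12 * 12 * 2)
    expect_lt(abs(ph$sdds$n_voxels[k] - analytic) / analytic, 0.1)
    # brute force: enumerate voxels inside the ball around the centre
    cx <- cfg$sdds$x_um[k] / 12; cy <- cfg$sdds$y_um[k] / 12
    ix <- round(cx) + 1; iy <- round(cy) + 1
    cz <- ph$surfaces$rpe[ix, iy] - 9 - r
    cnt <- 0L
    for (gx in floor(cx - r / 12):ceiling(cx + r / 12))
      for (gy in floor(cy - r / 12):ceiling(cy + r / 12))
        for (gz in floor((cz - r) / 2):ceiling((cz + r) / 2)) {
          if ((12 * (gx - cx))^2 + (12 * (gy - cy))^2 + (2 * gz - cz)^2 <= r^2)
            cnt <- cnt + 1L
        }
    expect_equal(ph$sdds$n_voxels[k], cnt)
  }
})

test_that("zero-parameter motion traces are identically zero", {
  tr <- simulate_motion(2.4, motion_params(drift_sd_um_rts = 0,
                                           axial_sd_um_rts = 0,
                                           saccade_rate_hz = 0), seed = 5)
  d <- eval_trace(tr, seq(0, 2.4, by = 0.1))
  expect_equal(max(abs(d)), 0)
})

test_that("saccade counts follow the configured Poisson rate", {
  # Monte-Carlo mean versus the Poisson expectation 0.5/s * 2.4 s = 1.2
  params <- motion_params(drift_sd_um_rts = 0, axial_sd_um_rts = 0,
                          saccade_rate_hz = 0.5)
  n_rep <- 10000L
  counts <- vapply(seq_len(n_rep), function(s)
    length(simulate_motion(2.4, params, seed = s,
                           resolution_s = 0.1)$saccade_times),
    numeric(1))
  se <- sqrt(1.2 / n_rep)
  expect_lt(abs(mean(counts) - 1.2), 3 * se)
})

test_that("traces step at saccades and are continuous in between", {
  params <- motion_params(drift_sd_um_rts = 3, saccade_rate_hz = 2,
                          saccade_amp_um = 80, saccade_amp_sd_um = 5)
  tr <- simulate_motion(2.4, params, seed = 9)
  expect_gt(length(tr$saccade_times), 0)
  ts <- tr$saccade_times[1]
  jump <- eval_trace(tr, ts + 1e-6) - eval_trace(tr, ts - 1e-6)
  amp <- sqrt(sum(jump^2))
  expect_gt(amp, 40)  # approximately the drawn amplitude (80 +/- 5 sd)
  expect_lt(amp, 120)
  # between saccades: displacement over a shrinking interval tends to 0
  tmid <- ts / 2
  d1 <- max(abs(eval_trace(tr, tmid + 1e-3) - eval_trace(tr, tmid)))
  d2 <- max(abs(eval_trace(tr, tmid + 1e-5) - eval_trace(tr, tmid)))
  expect_lt(d2, d1 + 1e-9)
  expect_lt(d2, 0.1)
})

test_that("static noiseless acquisition is a pure resampling", {
  ph <- flat_phantom(40)
  vols <- clean_volumes(ph)
  expect_equal(max(abs(vols[[1]]$grid - ph$grid)), 0)
  # x-fast and y-fast volumes are transposes in the transverse plane
  expect_equal(aperm(vols[[2]]$grid, c(1, 3, 2)), vols[[1]]$grid)
})

test_that("a constant transverse displacement shifts the volume by its
           voxel equivalent", {
  ph <- textured_phantom(60)
  proto <- small_protocol(60, 1L)
  v0 <- acquire(ph, proto, list(constant_trace(0.5)),
                speckle_contrast = 0, detector_sd = 0)[[1]]
  v1 <- acquire(ph, proto, list(constant_trace(0.5, c(24, 0, 0))),
                speckle_contrast = 0, detector_sd = 0)[[1]]
  # cross-correlate mid-depth en face features along x: peak at +2 voxels
  ef0 <- apply(v0$grid[150:200, , ], c(2, 3), mean)
  ef1 <- apply(v1$grid[150:200, , ], c(2, 3), mean)
  ccs <- vapply(-4:4, function(s) {
    ia <- max(1, 1 + s):min(60, 60 + s)
    cor(as.numeric(ef1[ia, ]), as.numeric(ef0[ia - s, ]))
  }, numeric(1))
  expect_equal((-4:4)[which.max(ccs)], 2)
})

test_that("the default protocol reproduces the published geometry and timing", {
  p <- acquisition_protocol()
  expect_equal(p$spacing_um, 12)
  expect_equal(p$n_volumes, 6L)
  expect_equal(p$total_s, 14.6)
  expect_equal(p$directions, rep(c("x", "y"), 3))
  t6 <- ascan_times(p, 6L)
  expect_lt(max(t6), 14.6)
  expect_equal(volume_start(p, 6) + p$vol_duration_s, 14.6)
  # timestamps strictly increase in acquisition order
  expect_true(all(diff(as.numeric(t6)) > 0))
})

test_that("blink injection sets whole B-scans to the floor and is recoverable", {
  ph <- flat_phantom(40)
  vol <- clean_volumes(ph, 1L)[[1]]
  expect_identical(inject_blinks(vol, list())$grid, vol$grid)
  vb <- inject_blinks(vol, list(11:15, 14:20))
  means <- apply(vb$grid, 3, mean)
  expect_equal(unname(which(means == 0.002)), 11:20)  # overlapping ranges merged
  expect_identical(detect_blinks(vb), 11:20)
})

test_that("seeded simulation is bit-reproducible", {
  ph1 <- textured_phantom(60)
  ph2 <- make_phantom(phantom_config(nx = 60, ny = 60, nz = 224,
                                     undulation_um = 25))
  expect_identical(ph1$grid, ph2$grid)
  proto <- small_protocol(60, 2L)
  tr <- lapply(1:2, function(v) simulate_motion(0.5, motion_params(), seed = v))
  a1 <- acquire(ph1, proto, tr, seed = 4)
  a2 <- acquire(ph2, proto, tr, seed = 4)
  expect_identical(a1[[2]]$grid, a2[[2]]$grid)
})
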