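zero_model <- function(protocol, n_volumes = 2L) {
  structure(list(
    times = lapply(seq_len(n_volumes), function(v)
      colMeans(ascan_times(protocol, v))),
    disp = lapply(seq_len(n_volumes), function(v)
      matrix(0, protocol$n_bscans, 3)),
    order = 3L, protocol = protocol, objective = 0, converged = TRUE,
    opts = motion_opts()), class = "displacement_model")
}

test_that("displacement evaluation interpolates control points exactly", {
  p <- small_protocol(10, 1L, vol_duration_s = 1)
  m <- zero_model(p, 1L)
  expect_equal(max(abs(eval_displacement(m, 1, seq(0, 1, 0.1)))), 0)
  # linear order: exact at control times, mean at midpoints
  m$order <- 1L
  m$disp[[1]][, 1] <- seq(0, 90, length.out = 10)
  tt <- m$times[[1]]
  expect_equal(unname(eval_displacement(m, 1, tt[4])[1, 1]), m$disp[[1]][4, 1])
  mid <- (tt[4] + tt[5]) / 2
  expect_equal(unname(eval_displacement(m, 1, mid)[1, 1]),
               mean(m$disp[[1]][4:5, 1]))
  # cubic order is also exact at control times
  m$order <- 3L
  expect_equal(unname(eval_displacement(m, 1, tt[7])[1, 1]), m$disp[[1]][7, 1])
  expect_error(eval_displacement(m, 1, 1.5), "outside")
})

test_that("geometric correction shifts positions by minus the displacement", {
  ph <- flat_phantom(40)
  vol <- clean_volumes(ph, 1L)[[1]]
  p <- vol$protocol
  m <- zero_model(p, 1L)
  s0 <- correct_volume(vol, m)
  pos <- octfuse:::nominal_positions(vol)
  expect_equal(s0$x_um, pos$x)
  expect_equal(s0$y_um, pos$y)
  expect_equal(unique(s0$z_off_um), 0)
  m$disp[[1]] <- matrix(rep(c(24, 0, 0), each = p$n_bscans), p$n_bscans, 3)
  s1 <- correct_volume(vol, m)
  expect_equal(s1$x_um, pos$x - 24)
  expect_equal(s1$y_um, pos$y)
  # intensities untouched
  expect_identical(s1$intensity, s0$intensity)
})

test_that("correcting with the ground-truth trace recovers the static scan", {
  ph <- textured_phantom(60)
  p <- small_protocol(60, 1L)
  tr <- simulate_motion(p$vol_duration_s, motion_params(drift_sd_um_rts = 12),
                        seed = 21)
  vol <- acquire(ph, p, list(tr), speckle_contrast = 0, detector_sd = 0)[[1]]
  s <- correct_volume(vol, tr)
  sc <- octfuse:::scatter_samples(list(s), 224, 60, 60, 2, 12)
  regridded <- octfuse:::value_grid(sc$sum, sc$wsum)
  ok <- is.finite(regridded)
  err <- abs(regridded[ok] - ph$grid[ok])
  # interpolation tolerance: sub-voxel resampling of a banded grid
  expect_lt(median(err), 0.02)
  expect_lt(mean(err > 0.1), 0.05)
})

test_that("static noiseless volumes yield near-zero estimated motion", {
  ph <- textured_phantom(60)
  vols <- clean_volumes(ph, 2L)
  model <- suppressWarnings(estimate_motion(vols))
  expect_lt(max(abs(do.call(rbind, model$disp))), 1.0)
})

test_that("the registration objective is gauge invariant and non-increasing
           across multi-resolution stages", {
  ph <- textured_phantom(60)
  p <- small_protocol(60, 2L)
  traces <- lapply(1:2, function(v)
    simulate_motion(p$vol_duration_s, motion_params(), seed = 30 + v))
  vols <- acquire(ph, p, traces, seed = 2)
  model <- suppressWarnings(estimate_motion(vols))
  expect_true(all(diff(model$objective) <= 1e-12))
  # gauge: shifting every volume by one voxel leaves the objective within
  # boundary-resampling tolerance
  j0 <- registration_objective(vols, model)
  shifted <- model
  shifted$disp <- lapply(model$disp, function(m) sweep(m, 2, c(-12, 0, 0)))
  j1 <- registration_objective(vols, shifted)
  expect_lt(abs(j1 - j0) / j0, 0.1)
  expect_lt(j0, registration_objective(vols, NULL))
})

test_that("drift motion is recovered to a few microns at reduced scale", {
  ph <- textured_phantom(80, und = 25)
  p <- small_protocol(80, 2L, vol_duration_s = 2.4)
  traces <- lapply(1:2, function(v)
    simulate_motion(p$vol_duration_s,
                    motion_params(drift_sd_um_rts = 10, axial_sd_um_rts = 2),
                    seed = 40 + v))
  vols <- acquire(ph, p, traces, seed = 8)
  model <- suppressWarnings(estimate_motion(vols))
  err <- motion_error(model, traces, p)
  expect_lt(err, 8)  # transverse voxel is 12 um
})

test_that("fewer than two usable volumes or one-direction input errors", {
  ph <- flat_phantom(40)
  vols <- clean_volumes(ph, 2L)
  expect_error(estimate_motion(vols[1]), "direction|usable")
  v2 <- vols[[1]]; v2$index <- 2L
  expect_error(estimate_motion(list(vols[[1]], v2)), "direction")
})
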