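test_that("BrM is recovered within one axial voxel on a flat phantom", {
  ph <- flat_phantom(40)
  vol <- clean_volumes(ph, 1L)[[1]]
  s <- segment_surface(vol, "brm")
  expect_lt(max(abs(s$depth_um - 382)), 2)
})

test_that("BrM RMSE stays within one axial voxel on undulating phantoms", {
  ph <- make_phantom(phantom_config(nx = 80, ny = 80, nz = 224,
                                    undulation_um = 40))
  vol <- acquire(ph, small_protocol(80, 1L), NULL, speckle_contrast = 0.35,
                 detector_sd = 0.01, seed = 6)[[1]]
  s <- segment_surface(vol, "brm")
  err <- s$depth_um - ph$surfaces$brm
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("BrM stays put under a druse while the posterior RPE is elevated", {
  ph <- make_phantom(phantom_config(
    nx = 80, ny = 80, nz = 224, undulation_um = 0,
    drusen = data.frame(x_um = 480, y_um = 480, r_um = 150, h_um = 60)))
  vol <- clean_volumes(ph, 1L)[[1]]
  brm <- segment_surface(vol, "brm")
  under <- abs(brm$depth_um - 382)   # pre-druse flat BrM depth
  expect_lt(max(under), 2)
  prpe <- segment_surface(vol, "prpe")
  centre <- prpe$depth_um[41, 41]
  expect_lt(centre, 330)  # elevated by ~60 um above the flat pRPE at 371
})

test_that("mean_surface averages depths and undoes axial shifts", {
  ph <- flat_phantom(40)
  vols <- clean_volumes(ph, 2L)
  s1 <- segment_surface(vols[[1]], "brm")
  s2 <- segment_surface(vols[[2]], "brm")
  # identical surfaces, zero motion: average equals input
  avg <- mean_surface(list(s1, s1), NULL)
  expect_equal(avg$depth_um[avg$valid], s1$depth_um[avg$valid],
               tolerance = 1e-6)
  # two flat synthetic surfaces at 298 and 302 average to 300
  sa <- s1; sa$depth_um[] <- 298
  sb <- s1; sb$depth_um[] <- 302
  expect_equal(unique(round(mean_surface(list(sa, sb), NULL)$depth_um[
    mean_surface(list(sa, sb), NULL)$valid], 9)), 300)
  # +10 um axial shift in one volume's trace is undone by the correction
  tr <- list(constant_trace(0.5), constant_trace(0.5, c(0, 0, 10)))
  vs <- acquire(ph, small_protocol(40, 2L), tr, speckle_contrast = 0,
                detector_sd = 0)
  surfs <- lapply(vs, segment_surface, layer = "brm")
  m <- structure(list(times = lapply(1:2, function(v)
    colMeans(ascan_times(vs[[v]]$protocol, v))),
    disp = list(matrix(0, 40, 3),
                matrix(rep(c(0, 0, 10), each = 40), 40, 3)),
    order = 1L, protocol = vs[[1]]$protocol, objective = 0,
    converged = TRUE, opts = NULL), class = "displacement_model")
  avg2 <- mean_surface(surfs, m)
  err <- avg2$depth_um[avg2$valid] - 382
  expect_lt(max(abs(err)), 2)
})

test_that("single-volume zero-motion fusion is an axial shift of the input", {
  ph <- flat_phantom(40)
  vol <- clean_volumes(ph, 1L)[[1]]
  s <- correct_volume(vol)
  # exact flat reference at the true BrM depth: the flattening shift is an
  # integer number of voxels, so interior voxels move without resampling
  refc <- structure(list(depth_um = matrix(382, 40, 40),
                         valid = matrix(TRUE, 40, 40), layer = "brm",
                         dz_um = 2, fused = TRUE, direction = NA_character_,
                         volume = NA_integer_, protocol = vol$protocol,
                         pitch_um = 12), class = "oct_surface")
  fused <- flatten_and_merge(list(s), refc)
  shift <- fused$target_idx - 382 / 2
  expect_equal(shift, round(shift))
  inner <- 60:210
  expect_equal(fused$intensity[inner + shift, 3, 3], vol$grid[inner, 3, 3],
               tolerance = 1e-9)
  expect_error(flatten_and_merge(list(), refc), "no samples")
})

test_that("six-volume fusion averages background noise below half the
           single-volume level", {
  fx <- fuse_fixture()
  bgF <- fx$fused$intensity[1:30, , ]
  bg1 <- fx$vols[[1]]$grid[1:30, , ]
  ratio <- sd(bgF[is.finite(bgF)]) / sd(bg1)
  expect_lt(ratio, 0.5)
})

test_that("re-segmenting the fused volume finds BrM at the target depth", {
  fx <- fuse_fixture()
  s2 <- segment_surface(fx$fused, "brm")
  dev <- abs(s2$depth_um - fx$fused$target_idx * fx$fused$dz_um)
  expect_lt(quantile(dev, 0.99, names = FALSE), 2.5)
  expect_lt(median(dev), 2)
})

test_that("fusion conserves intensity mass within interpolation tolerance", {
  fx <- fuse_fixture()
  # restrict to samples flattened well inside the axial range
  tot_in <- sum(vapply(fx$samples, function(s) sum(s$intensity), numeric(1)))
  tot_out <- sum(fx$fused$intensity * fx$fused$counts, na.rm = TRUE)
  expect_lt(abs(tot_out - tot_in) / tot_in, 0.05)
})

test_that("flattening never alters transverse positions", {
  fx <- fuse_fixture()
  # en face mean positions of a bright SDD-free grid: compare transverse
  # marginal profiles of input and fused volume
  s <- fx$samples[[1]]
  prof_in <- tapply(colSums(s$intensity), s$bscan, mean)
  vol_fused <- fx$fused$intensity
  prof_out <- apply(vol_fused, 3, function(m)
    mean(colSums(m, na.rm = TRUE)))
  # same slow-axis structure (correlation, not equality: fusion mixes
  # volumes)
  expect_gt(cor(as.numeric(prof_in), prof_out[as.integer(names(prof_in))]),
            0.9)
  expect_identical(dim(vol_fused)[2:3], dim(fx$ph$grid)[2:3])
})

test_that("fusing one flattened volume with unit counts reproduces it", {
  fx <- fuse_fixture()
  f1 <- flatten_and_merge(fx$samples[1], fx$ref)
  # feed the fused result back through with a flat reference at the target
  flatref <- fx$ref
  flatref$depth_um[] <- f1$target_idx * f1$dz_um
  flatref$valid[] <- TRUE
  s2 <- structure(list(
    intensity = matrix(f1$intensity, dim(f1$intensity)[1]),
    x_um = rep((0:79) * 12, times = 80),
    y_um = rep((0:79) * 12, each = 80),
    z_off_um = rep(0, 6400), bscan = rep(1:80, each = 80),
    volume = 1L, direction = "x", dz_um = 2, pitch_um = 12,
    protocol = fx$proto), class = "corrected_samples")
  s2$intensity[!is.finite(s2$intensity)] <- NA
  f2 <- flatten_and_merge(list(s2), flatref, nz = dim(f1$intensity)[1])
  where1 <- abs(f1$counts - 1) < 1e-6 & abs(f2$counts - 1) < 1e-6
  expect_gt(mean(where1), 0.2)
  expect_equal(f2$intensity[where1], f1$intensity[where1], tolerance = 1e-9)
})
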