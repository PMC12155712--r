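test_that("the default slab is 50 um thick from 27 to 77 um above BrM", {
  sp <- slab_spec()
  expect_equal(sp$reference, "brm")
  expect_equal(sp$lower_um, 27)
  expect_equal(sp$upper_um, 77)
  expect_equal(sp$thickness_um, 50)
  expect_error(slab_spec(lower_um = 80, upper_um = 70))
})

test_that("a uniform volume projects to a uniform slab", {
  p <- small_protocol(20, 1L)
  fused <- structure(list(
    intensity = array(0.7, c(100, 20, 20)),
    counts = array(1, c(100, 20, 20)),
    target_idx = 75L, reference = "brm", dz_um = 2, pitch_um = 12,
    protocol = p), class = "fused_volume")
  slab <- make_slab(fused)
  expect_equal(unique(as.numeric(slab$img)), 0.7)
  expect_identical(dim(slab$img), c(20L, 20L))
  # slab outside the axial range errors
  expect_error(make_slab(fused, slab_spec(lower_um = 27, upper_um = 600)),
               "axial")
  # reference mismatch errors
  expect_error(make_slab(fused, slab_spec("prpe")), "re-flatten")
})

test_that("slab values equal a brute-force loop over in-range voxels", {
  fx <- fuse_fixture()
  slab <- make_slab(fx$fused)
  fused <- fx$fused
  ref_um <- fused$target_idx * fused$dz_um
  nz <- dim(fused$intensity)[1]
  for (ix in c(1, 17, 53, 80)) for (iy in c(2, 40, 79)) {
    vals <- c(); n <- 0
    for (k in seq_len(nz)) {
      off <- ref_um - (k - 1) * fused$dz_um
      if (off >= 27 && off < 77 && fused$counts[k, ix, iy] > 0 &&
          is.finite(fused$intensity[k, ix, iy])) {
        vals <- c(vals, fused$intensity[k, ix, iy]); n <- n + 1
      }
    }
    expected <- if (n > 0) mean(vals) else NA_real_
    expect_equal(slab$img[ix, iy], expected, tolerance = 1e-12)
  }
})

test_that("sub-slab means combine to the full slab mean (interval partition)", {
  fx <- fuse_fixture()
  full <- make_slab(fx$fused, slab_spec(lower_um = 27, upper_um = 77))
  lo <- make_slab(fx$fused, slab_spec(lower_um = 27, upper_um = 51))
  hi <- make_slab(fx$fused, slab_spec(lower_um = 51, upper_um = 77))
  count_in <- function(l, u) {
    ref_um <- fx$fused$target_idx * fx$fused$dz_um
    off <- ref_um - (seq_len(dim(fx$fused$intensity)[1]) - 1) * fx$fused$dz_um
    rows <- which(off >= l & off < u)
    colSums(fx$fused$counts[rows, , ] > 0 &
              is.finite(fx$fused$intensity[rows, , ]))
  }
  nlo <- count_in(27, 51); nhi <- count_in(51, 77)
  combo <- (lo$img * nlo + hi$img * nhi) / (nlo + nhi)
  ok <- is.finite(full$img) & is.finite(combo)
  expect_gt(mean(ok), 0.9)
  expect_equal(full$img[ok], combo[ok], tolerance = 1e-9)
})

test_that("inserting a brighter voxel in the interval never lowers the slab", {
  p <- small_protocol(10, 1L)
  fused <- structure(list(
    intensity = array(0.4, c(100, 10, 10)),
    counts = array(1, c(100, 10, 10)),
    target_idx = 75L, reference = "brm", dz_um = 2, pitch_um = 12,
    protocol = p), class = "fused_volume")
  s0 <- make_slab(fused)
  set.seed(1)
  for (i in 1:20) {
    f2 <- fused
    k <- sample(which(75 * 2 - (seq_len(100) - 1) * 2 >= 27 &
                        75 * 2 - (seq_len(100) - 1) * 2 < 77), 1)
    ix <- sample(10, 1); iy <- sample(10, 1)
    f2$intensity[k, ix, iy] <- f2$intensity[k, ix, iy] + runif(1, 0, 2)
    s2 <- make_slab(f2)
    expect_gte(s2$img[ix, iy], s0$img[ix, iy])
  }
})

test_that("batch slabs are co-registered and drusen vanish under pRPE
           referencing", {
  ph <- make_phantom(phantom_config(
    nx = 80, ny = 80, nz = 224, undulation_um = 0,
    drusen = data.frame(x_um = 480, y_um = 480, r_um = 150, h_um = 40)))
  proto <- small_protocol(80, 2L)
  vols <- acquire(ph, proto, NULL, speckle_contrast = 0, detector_sd = 0)
  samples <- lapply(vols, correct_volume)
  fused_brm <- fuse_to_reference(vols, samples, NULL, "brm")
  fused_prpe <- fuse_to_reference(vols, samples, NULL, "prpe")
  specs <- list(slab_spec("brm"), slab_spec("prpe"))
  slabs <- compare_slabs(specs, list(brm = fused_brm, prpe = fused_prpe))
  # identical specs give identical images
  twice <- compare_slabs(list(slab_spec(), slab_spec()), fused_brm)
  expect_identical(twice[[1]]$img, twice[[2]]$img)
  # druse contrast: visible in the BrM slab, suppressed in the pRPE slab
  centre <- 36:46; rim <- c(1:10, 70:80)
  contrast <- function(img) {
    mean(img[centre, centre], na.rm = TRUE) -
      mean(img[rim, rim], na.rm = TRUE)
  }
  c_brm <- abs(contrast(slabs[[1]]$img))
  c_prpe <- abs(contrast(slabs[[2]]$img))
  expect_gt(c_brm, 0.04)
  expect_lt(c_prpe, 0.5 * c_brm)
})
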