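test_that("noiseless step A-scans are segmented at the exact step", {
  vol <- step_volume(2, 3, 16, d = 6)
  surf <- segment_ilm(vol, lateral_window = 1L)
  expect_true(all(surf$depth_index == 6L))
  expect_equal(surf$n_failed, 0L)

  # an all-zero A-scan in the same volume fails, others unaffected
  vol$intensities[1, 2, ] <- 0
  surf2 <- segment_ilm(vol, lateral_window = 1L)
  expect_true(is.na(surf2$depth_index[1, 2]))
  expect_equal(surf2$n_failed, 1L)
  expect_true(all(surf2$depth_index[-2] == 6L, na.rm = TRUE))

  # all-zero volume: everything fails and the volume is flagged unusable
  zvol <- raw_oct_volume(array(0, c(2, 3, 16)), 3.9, 11.7)
  zs <- segment_ilm(zvol)
  expect_equal(zs$failure_fraction, 1)
  expect_true(attr(zs, "volume_failed"))
})

test_that("contrast-adjusted volumes are refused", {
  vol <- contrast_adjust(step_volume(2, 2, 16, d = 6, v0 = 0.1, v1 = 0.9))
  expect_error(segment_ilm(vol), "raw data")
})

test_that("segmentation is translation-equivariant and gain-invariant", {
  p <- phantom_params(n_bscans = 4L, n_ascans = 8L, n_depth = 96L,
                      noise_sigma = 0.05)
  ph <- generate_volume(p, seed = 9)
  surf <- segment_ilm(ph$volume)

  # gain invariance: multiply intensities by c > 0
  vol_scaled <- raw_oct_volume(ph$volume$intensities * 7.3,
                               p$axial_spacing_um, p$lateral_spacing_um)
  expect_identical(segment_ilm(vol_scaled)$depth_index, surf$depth_index)

  # translation: shift all content deeper by s, pad the top with vitreous
  # (noise-free phantom so the padded pixels match the vitreous exactly)
  p0 <- phantom_params(n_bscans = 4L, n_ascans = 8L, n_depth = 96L,
                       noise_sigma = 0)
  ph0 <- generate_volume(p0, seed = 9)
  surf0 <- segment_ilm(ph0$volume)
  s <- 5L
  v <- ph0$volume$intensities
  nd <- dim(v)[3]
  shifted <- array(p0$baseline + p0$haze_level, dim(v))
  shifted[, , (s + 1):nd] <- v[, , 1:(nd - s)]
  surf_s <- segment_ilm(raw_oct_volume(shifted, p0$axial_spacing_um,
                                       p0$lateral_spacing_um))
  expect_identical(surf_s$depth_index, surf0$depth_index + s)
})

test_that("phantom ILM is recovered within 2 px under speckle", {
  maes <- vapply(1:10, function(seed) {
    p <- phantom_params(n_bscans = 8L, n_ascans = 32L, n_depth = 96L,
                        noise_sigma = 0.05)
    ph <- generate_volume(p, seed = seed)
    surf <- segment_ilm(ph$volume)
    mean(abs(surf$depth_index - ph$truth$ilm_depth), na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(maes), 2)
  # per-A-scan detection agrees exactly with the sidecar truth at zero
  # noise (no lateral smoothing, which legitimately rounds off the foveal
  # pit by a pixel)
  p0 <- phantom_params(n_bscans = 6L, n_ascans = 16L, n_depth = 96L,
                       noise_sigma = 0, haze_level = 0.02)
  ph0 <- generate_volume(p0, seed = 1)
  surf0 <- segment_ilm(ph0$volume, lateral_window = 1L)
  expect_equal(surf0$depth_index, ph0$truth$ilm_depth, ignore_attr = TRUE)
})

test_that("surface smoothing is a NA-aware 2-D median", {
  flat <- ilm_surface(matrix(20L, 8, 10), 64)
  expect_identical(surface_smooth(flat, 3)$depth_index, flat$depth_index)

  spiky <- matrix(20L, 8, 10); spiky[4, 5] <- 40L
  sm <- surface_smooth(ilm_surface(spiky, 64), 3)
  expect_true(all(sm$depth_index == 20L))

  set.seed(14)
  m <- matrix(sample(10:30, 15 * 20, replace = TRUE), 15, 20)
  m[sample(length(m), 25)] <- NA  # ~8% failed
  for (w in c(3L, 5L)) {
    sm <- surface_smooth(ilm_surface(m, 64), w)
    expect_identical(sm$depth_index, naive_median_filter(m, w))
  }
  expect_error(surface_smooth(flat, 4), "odd")
})

test_that("surfaces round-trip through CSV with failure flags", {
  m <- matrix(c(5L, NA, 7L, 8L, NA, 10L), 2, 3)
  path <- tempfile(fileext = ".csv")
  write_ilm_surface(ilm_surface(m, 16), path)
  back <- read_ilm_surface(path, 16)
  expect_identical(back$depth_index, m)
  expect_equal(back$n_failed, 2L)
})
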