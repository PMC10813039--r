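test_that("haze score matches hand-computed pooled means", {
  # constant volume: identical means above and below
  cv <- raw_oct_volume(array(0.7, c(2, 3, 10)), 3.9, 11.7)
  surf <- ilm_surface(matrix(5L, 2, 3), 10)
  sc <- compute_vh(cv, surf)
  expect_equal(sc$ratio, 1)
  expect_equal(sc$log_ratio, log(1 + 1e-6))

  # dark vitreous, bright retina
  sv <- step_volume(2, 3, 10, d = 5, v0 = 0, v1 = 1)
  expect_equal(compute_vh(sv, ilm_surface(matrix(5L, 2, 3), 10))$ratio, 0)

  # worked 1x2x4 example: vitreous (1,1)+(1,3), below all 4s
  arr <- array(0, c(1, 2, 4))
  arr[1, 1, ] <- c(1, 1, 4, 4)
  arr[1, 2, ] <- c(1, 3, 4, 4)
  vol <- raw_oct_volume(arr, 3.9, 11.7)
  sc <- compute_vh(vol, ilm_surface(matrix(3L, 1, 2), 4))
  expect_equal(sc$ratio, 1.5 / 4)
  expect_equal(sc$n_vitreous_px, 4L)
  expect_equal(sc$n_below_px, 4L)
})

test_that("degenerate scores raise the documented errors", {
  sv <- step_volume(2, 3, 10, d = 5)
  expect_error(compute_vh(sv, ilm_surface(matrix(1L, 2, 3), 10)),
               "no vitreous")
  zvol <- raw_oct_volume(array(0, c(2, 3, 10)), 3.9, 11.7)
  expect_error(compute_vh(zvol, ilm_surface(matrix(5L, 2, 3), 10)),
               "undefined score")
  adj <- contrast_adjust(step_volume(2, 3, 10, d = 5, v0 = 0.1, v1 = 0.9))
  expect_error(compute_vh(adj, ilm_surface(matrix(5L, 2, 3), 10)),
               "raw data")
})

test_that("pooled means equal the naive double loop, with failed A-scans", {
  set.seed(42)
  for (i in 1:6) {
    arr <- array(runif(4 * 4 * 8, 0, 2), c(4, 4, 8))
    ilm <- matrix(sample(2:7, 16, replace = TRUE), 4, 4)
    if (i > 3) ilm[sample(16, 3)] <- NA  # failed A-scans excluded everywhere
    vol <- raw_oct_volume(arr, 3.9, 11.7)
    sc <- compute_vh(vol, ilm_surface(ilm, 8))
    expect_equal(sc$ratio, naive_vh(arr, ilm))
    expect_equal(sc$n_excluded_ascans, sum(is.na(ilm)))
  }
})

test_that("log transform is the documented epsilon policy", {
  expect_equal(log_transform(1), log(1 + 1e-6))
  expect_equal(log_transform(0), log(1e-6))
  expect_error(log_transform(-0.1), "non-negative")
  set.seed(3)
  r <- sort(runif(1000, 0, 3))
  expect_true(all(diff(log_transform(r)) > 0))
})

test_that("score is invariant to global gain and increasing in haze", {
  p <- phantom_params(n_bscans = 4L, n_ascans = 8L, n_depth = 64L,
                      noise_sigma = 0)
  hazes <- c(0, 0.02, 0.05, 0.1)
  scores <- vapply(hazes, function(h) {
    p$haze_level <- h
    ph <- generate_volume(p, seed = 1)
    surf <- segment_ilm(ph$volume)
    sc <- compute_vh(ph$volume, surf)
    # gain invariance on the same phantom
    scaled <- raw_oct_volume(ph$volume$intensities * 3.7,
                             p$axial_spacing_um, p$lateral_spacing_um)
    expect_equal(compute_vh(scaled, surf)$ratio, sc$ratio)
    sc$ratio
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("display contrast adjustment inflates sub-unity haze scores", {
  set.seed(77)
  for (seed in 1:8) {
    p <- phantom_params(n_bscans = 4L, n_ascans = 8L, n_depth = 64L,
                        noise_sigma = 0.05,
                        haze_level = runif(1, 0, 0.1))
    ph <- generate_volume(p, seed = seed)
    surf <- segment_ilm(ph$volume)
    raw_sc <- compute_vh(ph$volume, surf)
    adj_sc <- compute_vh(contrast_adjust(ph$volume), surf,
                         allow_adjusted = TRUE)
    expect_lt(raw_sc$ratio, 1)
    expect_gt(adj_sc$ratio, raw_sc$ratio)
  }
})
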