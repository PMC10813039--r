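small_params <- function(...) {
  phantom_params(n_bscans = 6L, n_ascans = 12L, n_depth = 64L, ...)
}

test_that("A-scan profiles place haze in the vitreous exactly", {
  p <- small_params(noise_sigma = 0)
  b <- vitrehaze:::boundaries_from_ilm(24L, p)
  vit <- seq_len(b[["ilm"]] - 1)

  prof0 <- generate_ascan_profile(b, p, haze_level = 0, noise_sigma = 0)
  expect_true(all(prof0[vit] == p$baseline))

  prof_h <- generate_ascan_profile(b, p, haze_level = 0.07, noise_sigma = 0)
  expect_equal(mean(prof_h[vit]), p$baseline + 0.07)
  # retina unchanged by haze
  expect_equal(prof_h[-vit], prof0[-vit])

  bad <- b; bad[2] <- bad[1]  # non-increasing
  expect_error(generate_ascan_profile(bad, p), "invalid geometry")
})

test_that("speckle noise is mean-preserving in the vitreous (Monte Carlo)", {
  p <- small_params()
  b <- vitrehaze:::boundaries_from_ilm(24L, p)
  vit <- seq_len(b[["ilm"]] - 1)
  set.seed(11)
  n_draws <- ceiling(1e4 / length(vit))
  draws <- unlist(lapply(seq_len(n_draws), function(i) {
    generate_ascan_profile(b, p, haze_level = 0.1, noise_sigma = 0.05)[vit]
  }))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - (p$baseline + 0.1)), 3 * se)
})

test_that("volumes are reproducible and match their truth sidecar", {
  p <- small_params(noise_sigma = 0.05)
  v1 <- generate_volume(p, seed = 5)
  v2 <- generate_volume(p, seed = 5)
  expect_identical(v1$volume$intensities, v2$volume$intensities)
  expect_identical(v1$truth$ilm_depth, v2$truth$ilm_depth)
  expect_false(identical(v1$volume$intensities,
                         generate_volume(p, seed = 6)$volume$intensities))

  # zero-noise render: first supra-baseline voxel of every A-scan is the ILM
  p0 <- small_params(noise_sigma = 0, haze_level = 0)
  ph <- generate_volume(p0, seed = 1)
  firsts <- apply(ph$volume$intensities, c(1, 2),
                  function(x) which(x != p0$baseline)[1])
  expect_equal(firsts, ph$truth$ilm_depth, ignore_attr = TRUE)
  # curved surface: foveal pit makes the centre deeper than the corners
  expect_gt(ph$truth$ilm_depth[3, 6], ph$truth$ilm_depth[1, 1])

  # flat ILM when the pit is disabled
  pf <- small_params(noise_sigma = 0, pit_frac = 0)
  phf <- generate_volume(pf, seed = 1)
  expect_equal(length(unique(as.vector(phf$truth$ilm_depth))), 1L)

  expect_error(phantom_params(n_depth = 4), "at least 8")
})

test_that("contrast adjustment follows the gamma map and is one-shot", {
  # constant volume stays constant
  cv <- raw_oct_volume(array(0.4, c(2, 2, 8)), 3.9, 11.7)
  adj <- contrast_adjust(cv)
  expect_true(all(adj$intensities == 1))
  expect_true(adj$is_contrast_adjusted)
  expect_error(contrast_adjust(adj), "already")

  # two-level volume: ratio 0.125 -> 0.125^0.5
  tv <- step_volume(2, 2, 8, d = 5, v0 = 0.1, v1 = 0.8)
  ta <- contrast_adjust(tv, gamma = 0.5)
  ratio_raw <- 0.1 / 0.8
  ratio_adj <- mean(ta$intensities[, , 1:4]) / mean(ta$intensities[, , 5:8])
  expect_equal(ratio_adj, ratio_raw^0.5, tolerance = 1e-12)
})

test_that("volume TIFF round trip preserves intensities and metadata", {
  p <- small_params(noise_sigma = 0.05)
  ph <- generate_volume(p, seed = 2)
  path <- tempfile(fileext = ".tiff")
  write_oct_volume(ph$volume, path)
  back <- read_oct_volume(path)
  expect_equal(back$intensities, ph$volume$intensities, tolerance = 1e-6)
  expect_equal(back$axial_spacing_um, ph$volume$axial_spacing_um)
  expect_false(back$is_contrast_adjusted)
})

test_that("cohort covariates reproduce configured moments", {
  cc <- cohort_config(n_patients = 2000L, n_controls = 600L)
  coh <- generate_cohort(cc, seed = 21)
  ms <- coh$subjects[coh$subjects$group == "MS", ]
  se_mean <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(ms$age) - cc$age_mean_ms), 3 * se_mean(ms$age))
  expect_lt(abs(sd(ms$age) - cc$age_sd_ms), 3 * cc$age_sd_ms / sqrt(2 * nrow(ms)))
  expect_lt(abs(mean(ms$disease_duration) - cc$duration_mean), 0.6)
  expect_true(all(ms$edss * 2 == round(ms$edss * 2)))

  # eye-level pRNFL group means reproduce the configured 10.5 um difference
  eyes <- coh$eyes
  dif <- mean(eyes$prnfl_um[eyes$group == "MS"]) -
    mean(eyes$prnfl_um[eyes$group == "HC"])
  se_dif <- sqrt(var(eyes$prnfl_um[eyes$group == "MS"]) / sum(eyes$group == "MS") +
                 var(eyes$prnfl_um[eyes$group == "HC"]) / sum(eyes$group == "HC"))
  expect_lt(abs(dif - (84.6 - 95.1)), 3 * se_dif)

  expect_identical(coh$eyes, generate_cohort(cc, seed = 21)$eyes)
})

test_that("inter-eye correlation of residual log-VH matches rho", {
  for (rho in c(0, 0.6)) {
    cc <- cohort_config(n_patients = 2000L, n_controls = 10L, rho = rho)
    coh <- generate_cohort(cc, seed = 31)
    e <- coh$eyes[coh$eyes$group == "MS", ]
    resid <- e$log_vh - e$true_eta
    r1 <- resid[e$eye == "OD"][order(e$subject_id[e$eye == "OD"])]
    r2 <- resid[e$eye == "OS"][order(e$subject_id[e$eye == "OS"])]
    expect_lt(abs(cor(r1, r2) - rho), 0.03)
  }
})

test_that("cohort config validation rejects bad inputs", {
  expect_error(cohort_config(rho = 1), "rho")
  expect_error(cohort_config(residual_sd = 0), "residual_sd")
  expect_error(cohort_config(age_sd_ms = -1), "SD")
  expect_error(cohort_config(edss_weights = c(0.5, 0.2, 0.2)), "sum to 1")
})
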