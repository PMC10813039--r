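test_that("QC accounting reproduces the study's inclusion arithmetic", {
  # 316 eligible patients: 18 both-eye QC failures, 8 pathology -> 290 in,
  # rejection rate 8.2%
  ms <- make_qc_tables(316, 18, 8)
  res <- apply_qc(ms$subjects, ms$eyes)
  expect_equal(nrow(res$subjects), 290L)
  expect_equal(res$report$excluded_qc, 18L)
  expect_equal(res$report$excluded_pathology, 8L)
  expect_equal(res$report$rejection_rate_pct, 8.2)

  # 87 eligible controls, 2 exclusions -> 85 included
  hc <- make_qc_tables(87, 1, 1, group = "HC", prefix = "H")
  res_hc <- apply_qc(hc$subjects, hc$eyes)
  expect_equal(nrow(res_hc$subjects), 85L)

  # no failures: everyone included, rate 0.0
  clean <- make_qc_tables(50, 0, 0)
  res0 <- apply_qc(clean$subjects, clean$eyes)
  expect_equal(nrow(res0$subjects), 50L)
  expect_equal(res0$report$rejection_rate_pct, 0)

  # a single failed eye keeps the subject but drops that eye record
  one <- make_qc_tables(10, 0, 0)
  one$eyes$qc_pass[1] <- FALSE
  res1 <- apply_qc(one$subjects, one$eyes)
  expect_equal(nrow(res1$subjects), 10L)
  expect_equal(nrow(res1$eyes), 19L)
})

test_that("EDSS stratification uses the 3.5 / 5.5 cut points", {
  s <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:6), group = "MS",
    edss = c(0, 3.5, 4.0, 5.5, 6.0, 8.0)
  )
  out <- stratify_edss(s)
  expect_equal(out$subjects$stratum,
               c("mild", "mild", "moderate", "moderate", "severe", "severe"))
  expect_error(stratify_edss(dplyr::mutate(s, edss = edss + 0.3)), "lattice")
  expect_error(stratify_edss(dplyr::mutate(s, edss = c(11, 2, 2, 2, 2, 2))),
               "lattice")

  # stratum percentages as printed: counts over included patients, 1 dp
  expect_equal(stratum_percentages(c(164, 64, 63), 290), c(56.6, 22.1, 21.7))

  empty <- stratify_edss(s[s$group == "HC", ])
  expect_equal(nrow(empty$summary), 0L)
})

test_that("Mann-Whitney U equals the pairwise-comparison oracle", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  same <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_equal(same$U, 3)
  expect_equal(same$p, 1)
  set.seed(20)
  for (i in 1:5) {
    a <- sample(1:15, 20, replace = TRUE)  # ties likely
    b <- sample(3:18, 20, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$U, naive_u(a, b))
    expect_true(res$p > 0 && res$p <= 1)
  }
})

test_that("chi-square test matches hand-computed O/E arithmetic", {
  prop <- rbind(c(10, 20), c(20, 40))  # perfectly proportional
  res <- chi_square_test(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  res2 <- chi_square_test(rbind(c(10, 20), c(20, 10)))
  expect_equal(res2$statistic, 20 / 3)
  expect_equal(res2$df, 1)

  # observed sex ratios (195:95 patients vs 53:32 controls): no evidence of
  # imbalance at alpha = 0.05
  sex <- rbind(c(195, 95), c(53, 32))
  res3 <- chi_square_test(sex)
  expect_gt(res3$p, 0.05)

  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "expected")
})

test_that("the association suite composes fit_gee verbatim", {
  coh <- generate_cohort(cohort_config(n_patients = 120L, n_controls = 40L),
                         seed = 33)
  res <- run_association_suite(
    coh$eyes, coh$subjects,
    covariates = list(gcipl_um = list(adjust = c("age", "sex"),
                                      cohorts = "MS")),
    stratify = FALSE
  )
  row <- res[res$covariate == "gcipl_um" & res$cohort == "MS", ]
  direct <- fit_gee(coh$eyes[coh$eyes$group == "MS", ],
                    log_vh ~ gcipl_um + age + sex)
  expect_equal(row$beta, direct$coefficients[["gcipl_um"]])
  expect_equal(row$se, direct$robust_se[["gcipl_um"]])
  expect_equal(row$p, direct$p_values[["gcipl_um"]])
  expect_equal(row$rho_hat, direct$rho_hat)
})

test_that("tiny strata are flagged not-estimable instead of fitted", {
  coh <- generate_cohort(cohort_config(n_patients = 30L, n_controls = 10L),
                         seed = 34)
  # force all but two MS subjects into the severe stratum being empty-ish:
  # run with a minimum larger than any stratum
  res <- run_association_suite(
    coh$eyes, coh$subjects,
    covariates = list(age = list(adjust = "sex", cohorts = "MS")),
    stratify = TRUE, min_clusters = 60L
  )
  strata_rows <- res[res$stratum != "all", ]
  expect_true(all(is.na(strata_rows$beta)))
  expect_true(all(grepl("not estimable", strata_rows$note)))
})
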