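#' Apply OCT quality control and pathology exclusions
#'
#' A subject is excluded when scans of both eyes fail quality control, or
#' when an excluding ocular pathology is flagged; a subject with a single
#' failed eye stays in the study with the remaining eye. The report counts
#' exclusions per reason (QC assessed first, pathology among the remainder)
#' and the rejection rate `excluded / eligible` in percent (1 decimal),
#' per group when a `group` column is present.
#'
#' @param subjects tibble with `subject_id`, optional `group` and logical
#'   `pathology` columns.
#' @param eyes tibble with `subject_id` and logical `qc_pass`, one or two
#'   rows per subject.
#' @return List: `subjects` (included subjects), `eyes` (their QC-passing
#'   eye records), `excluded` (subject ids with `excluded_reason`), and
#'   `report` (per-group counts and `rejection_rate_pct`).
#' @export
apply_qc <- function(subjects, eyes) {
  stopifnot("subject_id" %in% names(subjects), "subject_id" %in% names(eyes),
            "qc_pass" %in% names(eyes))
  if (!all(subjects$subject_id %in% eyes$subject_id)) {
    stop("every subject needs at least one eye record")
  }
  pathology <- if ("pathology" %in% names(subjects)) subjects$pathology else
    rep(FALSE, nrow(subjects))
  any_pass <- tapply(eyes$qc_pass, eyes$subject_id, any)
  qc_fail <- !any_pass[subjects$subject_id]
  reason <- ifelse(qc_fail, "both_eyes_qc_fail",
                   ifelse(pathology, "pathology", NA_character_))
  excluded <- !is.na(reason)

  grp <- if ("group" %in% names(subjects)) subjects$group else
    rep("all", nrow(subjects))
  report <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = grp, reason = reason,
                                   excluded = excluded), .data$group),
    n_eligible = dplyr::n(),
    excluded_qc = sum(.data$reason == "both_eyes_qc_fail", na.rm = TRUE),
    excluded_pathology = sum(.data$reason == "pathology", na.rm = TRUE),
    n_included = sum(!.data$excluded),
    rejection_rate_pct = round(100 * sum(.data$excluded) / dplyr::n(), 1),
    .groups = "drop"
  )
  inc <- subjects[!excluded, , drop = FALSE]
  list(
    subjects = inc,
    eyes = eyes[eyes$subject_id %in% inc$subject_id & eyes$qc_pass, ,
                drop = FALSE],
    excluded = tibble::tibble(subject_id = subjects$subject_id[excluded],
                              excluded_reason = reason[excluded]),
    report = report
  )
}

#' Stratify MS subjects by EDSS disability
#'
#' Labels each MS subject as mild (EDSS 0.0-3.5), moderate (4.0-5.5) or
#' severe (6.0-10) disability and tabulates counts with percentages of the
#' included MS patients (1 decimal). EDSS values must lie on the half-point
#' lattice in `[0, 10]`.
#'
#' @param subjects tibble with `edss` (and optionally `group`; only `"MS"`
#'   rows are stratified).
#' @return List: `subjects` (input plus a `stratum` column) and `summary`
#'   (tibble of `stratum`, `n`, `pct`).
#' @export
stratify_edss <- function(subjects) {
  stopifnot("edss" %in% names(subjects))
  ms <- if ("group" %in% names(subjects)) subjects$group == "MS" else
    rep(TRUE, nrow(subjects))
  e <- subjects$edss[ms]
  if (any(is.na(e))) stop("EDSS missing for an MS subject")
  if (any(e < 0 | e > 10 | abs(e * 2 - round(e * 2)) > 1e-9)) {
    stop("EDSS must be on the 0.5-point lattice within [0, 10]")
  }
  lab <- ifelse(e <= 3.5, "mild", ifelse(e <= 5.5, "moderate", "severe"))
  stratum <- rep(NA_character_, nrow(subjects))
  stratum[ms] <- lab
  lev <- c("mild", "moderate", "severe")
  counts <- vapply(lev, function(s) sum(lab == s), integer(1))
  summary <- tibble::tibble(
    stratum = lev,
    n = counts,
    pct = if (length(e)) stratum_percentages(counts, length(e)) else
      rep(NA_real_, 3)
  )
  if (length(e) == 0L) summary <- summary[0, ]
  list(subjects = dplyr::mutate(subjects, stratum = stratum),
       summary = summary)
}

#' Stratum percentages of the included cohort
#'
#' Percentage of included patients per stratum, rounded to 1 decimal:
#' `round(100 * counts / n_included, 1)`.
#'
#' @param counts integer vector of per-stratum counts.
#' @param n_included denominator (number of included patients).
#' @return Numeric vector of percentages, names preserved.
#' @export
stratum_percentages <- function(counts, n_included) {
  stopifnot(n_included > 0, all(counts >= 0))
  round(100 * counts / n_included, 1)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with a two-sided p-value from the tie-corrected
#' normal approximation with continuity correction (the test used for
#' non-normally distributed subject-level comparisons). When every value in
#' both samples is identical the test is degenerate; by convention
#' `U = n_a * n_b / 2` and `p = 1`.
#'
#' @param a,b non-empty numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson chi-square test for a 2 x k contingency table
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `k - 1` degrees of freedom
#' and an upper-tail chi-square p-value, without continuity correction
#' (used for categorical subject-level comparisons such as the sex ratio).
#'
#' @param tab 2 x k matrix of counts with all expected counts > 0.
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_test <- function(tab) {
  stopifnot(is.matrix(tab), nrow(tab) == 2, ncol(tab) >= 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("zero expected count in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# covariates reported by the association suite, with their adjustment sets
suite_covariates <- function() {
  list(
    age = list(adjust = "sex", cohorts = c("MS", "HC")),
    disease_duration = list(adjust = c("age", "sex"), cohorts = "MS"),
    sex = list(adjust = "age", cohorts = c("MS", "HC")),
    prnfl_um = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    gcipl_um = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    inl_um = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    ngmv_ml = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    nwmv_ml = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    nbv_ml = list(adjust = c("age", "sex"), cohorts = c("MS", "HC")),
    lesion_ml = list(adjust = c("age", "sex"), cohorts = "MS")
  )
}

# fit one GEE row of the association table, robust to small strata
suite_row <- function(dat, covariate, term, rhs, cohort, stratum,
                      min_clusters = 3L) {
  base <- tibble::tibble(
    cohort = cohort, stratum = stratum, covariate = covariate,
    n_obs = NA_integer_, n_clusters = NA_integer_,
    beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, rho_hat = NA_real_, converged = NA, note = NA_character_
  )
  vars <- unique(c(all.vars(stats::as.formula(paste("~", rhs))), "log_vh"))
  dat <- dat[stats::complete.cases(dat[, vars, drop = FALSE]), , drop = FALSE]
  n_cl <- length(unique(dat$subject_id))
  if (n_cl < min_clusters) {
    base$note <- "not estimable: fewer clusters than minimum"
    return(base)
  }
  fml <- stats::as.formula(paste("log_vh ~", rhs))
  fit <- tryCatch(suppressMessages(fit_gee(dat, fml)), error = identity)
  if (inherits(fit, "error")) {
    base$note <- paste("not estimable:", conditionMessage(fit))
    return(base)
  }
  if (!term %in% names(fit$coefficients)) {
    base$note <- paste("term absent from fit:", term)
    return(base)
  }
  tibble::tibble(
    cohort = cohort, stratum = stratum, covariate = covariate,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    beta = fit$coefficients[[term]], se = fit$robust_se[[term]],
    ci_low = fit$ci95_low[[term]], ci_high = fit$ci95_high[[term]],
    p = fit$p_values[[term]], rho_hat = fit$rho_hat,
    converged = fit$converged, note = NA_character_
  )
}

#' Eye-level association suite for log vitreous haze
#'
#' Runs the full set of exchangeable-GEE associations of log-VH: one model
#' per covariate (age, disease duration, sex, retinal layer thicknesses,
#' normalized brain volumes, lesion volume), each adjusted for age and sex
#' (the age model is adjusted for sex only, the sex model for age only),
#' separately in MS patients and healthy controls; MS-vs-HC and
#' phenotype-vs-HC group contrasts on the pooled table; and, optionally,
#' stratified reruns within each EDSS disability stratum. Only QC-passing
#' eyes of included subjects should be supplied (see [apply_qc()]).
#'
#' @param eyes eye-level tibble (two rows per subject) containing `log_vh`,
#'   `subject_id` and the covariate columns; columns missing from `eyes`
#'   are joined from `subjects`.
#' @param subjects optional subject-level tibble for the join.
#' @param covariates named list as produced by `suite_covariates()`;
#'   defaults to the full set.
#' @param stratify run the per-stratum MS analyses (default `TRUE`).
#' @param min_clusters smallest cluster count for which a row is estimated.
#' @return Tibble with one row per (cohort, stratum, covariate): `n_obs`,
#'   `n_clusters`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `rho_hat`,
#'   `converged`, `note`.
#' @export
run_association_suite <- function(eyes, subjects = NULL,
                                  covariates = suite_covariates(),
                                  stratify = TRUE, min_clusters = 3L) {
  stopifnot(all(c("subject_id", "log_vh") %in% names(eyes)))
  if (!is.null(subjects)) {
    extra <- setdiff(names(subjects), names(eyes))
    if (length(extra)) {
      eyes <- dplyr::left_join(eyes,
                               subjects[, c("subject_id", extra)],
                               by = "subject_id")
    }
  }
  if ("qc_pass" %in% names(eyes)) eyes <- eyes[eyes$qc_pass, , drop = FALSE]
  term_of <- function(cov) if (cov == "sex") "sexM" else cov

  rows <- list()
  for (cov in names(covariates)) {
    spec <- covariates[[cov]]
    rhs <- paste(unique(c(cov, spec$adjust)), collapse = " + ")
    for (g in spec$cohorts) {
      dat <- eyes[eyes$group == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        suite_row(dat, cov, term_of(cov), rhs, g, "all", min_clusters)
    }
  }

  # group contrasts against HC (pairwise models, HC as reference)
  contrasts <- list(MS = c("RRMS", "SPMS", "PPMS"),
                    RRMS = "RRMS", SPMS = "SPMS", PPMS = "PPMS")
  for (lbl in names(contrasts)) {
    keep <- eyes$group == "HC" |
      (eyes$group == "MS" & eyes$phenotype %in% contrasts[[lbl]])
    dat <- eyes[keep, , drop = FALSE]
    dat$is_case <- as.integer(dat$group == "MS")
    rows[[length(rows) + 1L]] <-
      suite_row(dat, paste0(lbl, "_vs_HC"), "is_case",
                "is_case + age + sex", "MS+HC", "all", min_clusters)
  }

  if (stratify && any(eyes$group == "MS")) {
    ms_subj <- unique(eyes[eyes$group == "MS",
                           c("subject_id", "edss", "group")])
    strat <- stratify_edss(ms_subj)$subjects
    eyes_ms <- dplyr::left_join(eyes[eyes$group == "MS", , drop = FALSE],
                                strat[, c("subject_id", "stratum")],
                                by = "subject_id")
    for (s in c("mild", "moderate", "severe")) {
      dat <- eyes_ms[eyes_ms$stratum == s, , drop = FALSE]
      for (cov in names(covariates)) {
        spec <- covariates[[cov]]
        if (!"MS" %in% spec$cohorts) next
        rhs <- paste(unique(c(cov, spec$adjust)), collapse = " + ")
        rows[[length(rows) + 1L]] <-
          suite_row(dat, cov, term_of(cov), rhs, "MS", s, min_clusters)
      }
    }
  }
  dplyr::bind_rows(rows)
}
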