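#' Pipeline run configuration
#'
#' Bundles everything a reproducible end-to-end run needs; a run is fully
#' determined by `(config, seed)`. Two profiles are available: `"tabular"`
#' (the cohort generator emits haze scores directly on the analysis scale;
#' fast, used for statistical work) and `"image"` (every eye is rendered as
#' an OCT phantom volume, ILM-segmented and scored from pixels; slower,
#' exercises the full imaging path).
#'
#' @param seed integer seed for the whole run.
#' @param profile `"tabular"` or `"image"`.
#' @param cohort a [cohort_config()].
#' @param phantom [phantom_params()] used per eye in the image profile
#'   (default small volumes to keep rendering affordable).
#' @param stratify run EDSS-stratified analyses (default `TRUE`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, profile = c("tabular", "image"),
                       cohort = cohort_config(),
                       phantom = phantom_params(n_bscans = 16L,
                                                n_ascans = 32L,
                                                n_depth = 64L),
                       stratify = TRUE) {
  profile <- match.arg(profile)
  stopifnot(inherits(cohort, "cohort_config"))
  if (cohort$n_patients < 1L || cohort$n_controls < 1L) {
    stop("run requires at least one patient and one control")
  }
  structure(
    list(seed = as.integer(seed), profile = profile, cohort = cohort,
         phantom = phantom, stratify = isTRUE(stratify)),
    class = "run_config"
  )
}

# haze level that makes a phantom's measured VH ratio approximate `target`:
# the sub-ILM mean of a clean rendered A-scan is the denominator the score
# will see, so haze = target * mean_below - baseline (clipped at 0).
haze_for_ratio <- function(target_ratio, params) {
  ilm <- max(round(params$ilm_frac * params$n_depth),
             as.integer(params$n_depth / 8) + 1L)
  b <- boundaries_from_ilm(ilm, params)
  prof <- generate_ascan_profile(b, params, haze_level = 0, noise_sigma = 0,
                                 read_noise_sd = 0)
  mu_below <- mean(prof[b[["ilm"]]:params$n_depth])
  pmax(target_ratio * mu_below - params$baseline, 0)
}

# replace each eye's haze score with one measured from a rendered phantom
score_eyes_from_phantoms <- function(eyes, phantom) {
  for (i in seq_len(nrow(eyes))) {
    p <- phantom
    p$haze_level <- haze_for_ratio(eyes$vh_ratio[i], phantom)
    ph <- generate_volume(p, seed = i)
    surf <- segment_ilm(ph$volume)
    sc <- compute_vh(ph$volume, surf)
    eyes$vh_ratio[i] <- sc$ratio
    eyes$log_vh[i] <- sc$log_ratio
  }
  eyes
}

cohort_summary_table <- function(subjects, eyes) {
  msd <- function(x) sprintf("%.1f (±%.1f)", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  per_group <- function(g) {
    s <- subjects[subjects$group == g, ]
    e <- eyes[eyes$group == g, ]
    c(
      n = as.character(nrow(s)),
      age = msd(s$age),
      `sex F:M` = paste(sum(s$sex == "F"), sum(s$sex == "M"), sep = ":"),
      `disease duration` = if (g == "MS") msd(s$disease_duration) else "N/A",
      `pRNFL (um)` = msd(e$prnfl_um),
      `mGCIPL (um)` = msd(e$gcipl_um),
      `mINL (um)` = msd(e$inl_um),
      `NGMV (mL)` = msd(s$ngmv_ml),
      `NWMV (mL)` = msd(s$nwmv_ml),
      `VH score` = sprintf("%.2f (±%.2f)", mean(e$vh_ratio),
                           stats::sd(e$vh_ratio))
    )
  }
  tibble::tibble(characteristic = names(per_group("MS")),
                 MS = unname(per_group("MS")),
                 HC = unname(per_group("HC")))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, in order: cohort simulation, (image profile only) phantom
#' rendering + ILM segmentation + pixel-level haze scoring per eye, quality
#' control, EDSS stratification, and the eye-level GEE association suite.
#' All tables, a markdown report (cohort summary, association table,
#' per-stratum haze means) and a manifest are written to `out_dir`.
#' Identical `(config, seed)` produce byte-identical result tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` runs in a
#'   temporary directory.
#' @return Invisibly, a list with the tables (`subjects`, `eyes`,
#'   `qc_report`, `strata`, `results`, `summary`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- tempfile("vitrehaze_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(...) message(sprintf("[%s] %s", format(Sys.time(), "%T"),
                                         sprintf(...)))

  stage("stage 1/5: simulating cohort (%d MS, %d HC, profile %s)",
        config$cohort$n_patients, config$cohort$n_controls, config$profile)
  cohort <- generate_cohort(config$cohort, seed = config$seed)

  if (config$profile == "image") {
    stage("stage 2/5: rendering and scoring %d phantom volumes",
          nrow(cohort$eyes))
    cohort$eyes <- score_eyes_from_phantoms(cohort$eyes, config$phantom)
  } else {
    stage("stage 2/5: tabular profile, using generated haze scores")
  }

  stage("stage 3/5: quality control")
  qc <- apply_qc(cohort$subjects, cohort$eyes)

  stage("stage 4/5: EDSS stratification")
  strat <- stratify_edss(qc$subjects)

  stage("stage 5/5: association suite")
  results <- run_association_suite(qc$eyes, qc$subjects,
                                   stratify = config$stratify)

  summary_tbl <- cohort_summary_table(qc$subjects, qc$eyes)
  stratum_vh <- dplyr::summarise(
    dplyr::group_by(
      dplyr::left_join(qc$eyes,
                       strat$subjects[, c("subject_id", "stratum")],
                       by = "subject_id"),
      .data$stratum),
    mean_vh = mean(.data$vh_ratio), sd_vh = stats::sd(.data$vh_ratio),
    n_eyes = dplyr::n(), .groups = "drop"
  )

  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
  w(cohort$subjects, "subjects.csv")
  w(cohort$eyes, "eyes.csv")
  w(qc$report, "qc_report.csv")
  w(strat$summary, "edss_strata.csv")
  w(results, "results.csv")

  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  res_md <- results
  report <- c(
    "# vitrehaze run report", "",
    sprintf("- seed: %d; profile: %s", config$seed, config$profile),
    sprintf("- included: %d subjects / %d eyes",
            nrow(qc$subjects), nrow(qc$eyes)), "",
    "## Cohort summary", "",
    knit_md_table(summary_tbl),
    "", "## Haze by disability stratum", "",
    knit_md_table(dplyr::mutate(stratum_vh,
                                mean_vh = fmt_num(.data$mean_vh),
                                sd_vh = fmt_num(.data$sd_vh))),
    "", "## Associations with log vitreous haze", "",
    knit_md_table(dplyr::mutate(
      res_md,
      dplyr::across(c("beta", "se", "ci_low", "ci_high", "rho_hat"), fmt_num),
      p = ifelse(is.na(.data$p), "NA", signif(.data$p, 3))
    ))
  )
  writeLines(report, file.path(out_dir, "report.md"))

  manifest <- list(
    package = "vitrehaze",
    version = as.character(utils::packageVersion("vitrehaze")),
    seed = config$seed,
    profile = config$profile,
    cohort_config = unclass(config$cohort),
    phantom_params = if (config$profile == "image") config$phantom else NULL,
    outputs = c("subjects.csv", "eyes.csv", "qc_report.csv",
                "edss_strata.csv", "results.csv", "report.md")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage("run complete: %s", out_dir)
  invisible(list(subjects = cohort$subjects, eyes = cohort$eyes,
                 qc_report = qc$report, strata = strat$summary,
                 results = results, summary = summary_tbl,
                 stratum_vh = stratum_vh, out_dir = out_dir))
}

# minimal markdown table renderer (avoids a knitr dependency)
knit_md_table <- function(df) {
  df <- as.data.frame(lapply(df, as.character), check.names = FALSE)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(hdr, sep, body)
}
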