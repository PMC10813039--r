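#' Compute the vitreous haze score of a volume
#'
#' The haze score is the ratio of the mean raw intensity of all vitreous
#' pixels (pixels strictly above the segmented ILM) to the mean intensity of
#' all pixels at or below the ILM, pooled over every non-failed A-scan of
#' every B-scan (grand means, not per-B-scan averages). Failed A-scans
#' contribute to neither mean. Because it is a ratio of means, the score is
#' invariant to any global intensity gain. The log score used in all
#' analyses is `log(ratio + eps)` (natural log, `eps = 1e-6`).
#'
#' The denominator is the full complement of the vitreous within the scan
#' (retina plus everything beneath); `denominator = "retina"` restricts it
#' to pixels between the ILM and a supplied lower boundary, for sensitivity
#' analysis.
#'
#' @param volume a raw [raw_oct_volume]; contrast-adjusted input is an
#'   error, since display transforms artificially inflate the vitreous
#'   signal.
#' @param surface matching [ilm_surface].
#' @param eps offset in the log transform.
#' @param denominator `"below_ilm"` (default: all pixels at/below the ILM)
#'   or `"retina"` (requires `lower_boundary`).
#' @param lower_boundary integer matrix `(b_scan, a_scan)` of exclusive
#'   lower depth bounds when `denominator = "retina"`.
#' @param allow_adjusted score a contrast-adjusted volume anyway (only for
#'   demonstrating how display transforms inflate the score; never for
#'   analysis).
#' @return Object of class `vh_score`: `ratio`, `log_ratio`,
#'   `n_vitreous_px`, `n_below_px`, `n_excluded_ascans`.
#' @export
compute_vh <- function(volume, surface, eps = 1e-6,
                       denominator = c("below_ilm", "retina"),
                       lower_boundary = NULL, allow_adjusted = FALSE) {
  stopifnot(inherits(volume, "raw_oct_volume"), inherits(surface, "ilm_surface"))
  denominator <- match.arg(denominator)
  if (volume$is_contrast_adjusted && !allow_adjusted) {
    stop("vitreous haze is defined on raw data; refusing a contrast-adjusted volume")
  }
  v <- volume$intensities
  nb <- dim(v)[1]; na_ <- dim(v)[2]; nd <- dim(v)[3]
  if (!all(dim(surface$depth_index) == c(nb, na_))) {
    stop("surface dimensions do not match volume")
  }
  ilm <- surface$depth_index
  ok <- !is.na(ilm)
  if (!any(ok)) stop("all A-scans failed segmentation; score undefined")

  depth <- array(rep(seq_len(nd), each = nb * na_), c(nb, na_, nd))
  ilm3 <- array(ilm, c(nb, na_, nd))
  ok3 <- array(ok, c(nb, na_, nd))
  vit <- ok3 & depth < ilm3
  below <- ok3 & depth >= ilm3
  if (denominator == "retina") {
    if (is.null(lower_boundary)) {
      stop("denominator = \"retina\" requires lower_boundary")
    }
    below <- below & depth <= array(lower_boundary, c(nb, na_, nd))
  }
  n_vit <- sum(vit); n_below <- sum(below)
  if (n_vit == 0L) {
    stop("no vitreous pixels (ILM at the top of the scan everywhere)")
  }
  denom <- mean(v[below])
  if (!is.finite(denom) || denom <= .Machine$double.eps) {
    stop("undefined score: sub-ILM mean intensity is zero")
  }
  ratio <- mean(v[vit]) / denom
  structure(
    list(
      ratio = ratio,
      log_ratio = log_transform(ratio, eps),
      n_vitreous_px = n_vit,
      n_below_px = n_below,
      n_excluded_ascans = sum(!ok)
    ),
    class = "vh_score"
  )
}

#' @export
print.vh_score <- function(x, ...) {
  cat(sprintf(
    "vh_score: ratio %.4f (log %.4f), %d vitreous px / %d below, %d A-scans excluded\n",
    x$ratio, x$log_ratio, x$n_vitreous_px, x$n_below_px, x$n_excluded_ascans
  ))
  invisible(x)
}

#' Log-transform a haze ratio
#'
#' Natural log of `ratio + eps`. The offset makes a zero ratio finite
#' (`log(eps)`) and is negligible at observed haze levels; the choice of
#' base only rescales regression coefficients.
#'
#' @param ratio non-negative haze ratio.
#' @param eps positive offset, default `1e-6`.
#' @return `log(ratio + eps)`, strictly increasing in `ratio`.
#' @export
log_transform <- function(ratio, eps = 1e-6) {
  if (any(ratio < 0)) stop("ratio must be non-negative")
  stopifnot(eps > 0)
  log(ratio + eps)
}
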