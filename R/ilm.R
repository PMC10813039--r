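#' Construct an ILM surface object
#'
#' Per-A-scan depth indices of the internal limiting membrane. Failed
#' A-scans (no detectable vitreous-to-retina transition) carry `NA` in the
#' depth matrix and are reported as `-1` in exported tables; they are
#' excluded from downstream vitreous-haze means rather than interpolated.
#'
#' @param depth_index integer matrix `(b_scan, a_scan)`; `NA` where failed.
#' @param n_depth depth extent of the source volume (for validation).
#' @return Object of class `ilm_surface` with fields `depth_index`,
#'   `n_failed` and `failure_fraction`.
#' @export
ilm_surface <- function(depth_index, n_depth) {
  stopifnot(is.matrix(depth_index))
  ok <- !is.na(depth_index)
  if (any(depth_index[ok] < 1 | depth_index[ok] > n_depth)) {
    stop("depth_index out of range")
  }
  structure(
    list(
      depth_index = depth_index,
      n_depth = as.integer(n_depth),
      n_failed = sum(!ok),
      failure_fraction = sum(!ok) / length(depth_index)
    ),
    class = "ilm_surface"
  )
}

#' @export
print.ilm_surface <- function(x, ...) {
  cat(sprintf("ilm_surface: %d x %d A-scans, %d failed (%.1f%%)\n",
              nrow(x$depth_index), ncol(x$depth_index), x$n_failed,
              100 * x$failure_fraction))
  invisible(x)
}

#' Segment the internal limiting membrane in a raw volume
#'
#' Per A-scan, intensities are median-3 smoothed along depth and the ILM is
#' taken as the first depth whose smoothed intensity rises more than `k`
#' robust SDs (1.4826 x MAD of the leading vitreous segment) above the
#' running vitreous baseline, an expanding median of all shallower samples.
#' An absolute floor of `1e-4 * max(volume)` breaks ties in noiseless data
#' while keeping the rule invariant to a global intensity gain. The raw
#' surface is then median-filtered laterally across neighbouring A-scans.
#' A-scans with no qualifying rise are flagged failed; if more than half of
#' all A-scans fail, the whole volume is flagged unusable.
#'
#' The detector assumes the leading ~1/8 of the depth range is vitreous;
#' scoring is only defined on raw (not contrast-adjusted) volumes.
#'
#' @param volume a raw [raw_oct_volume].
#' @param k rise threshold in robust SDs (default 4).
#' @param lateral_window odd lateral median-filter window (default 5);
#'   `1` disables surface smoothing.
#' @param max_failure_fraction volume-level failure threshold (default 0.5).
#' @return An [ilm_surface]; attribute `volume_failed` is `TRUE` when the
#'   failure fraction exceeds `max_failure_fraction`.
#' @export
segment_ilm <- function(volume, k = 4, lateral_window = 5L,
                        max_failure_fraction = 0.5) {
  stopifnot(inherits(volume, "raw_oct_volume"))
  if (volume$is_contrast_adjusted) {
    stop("vitreous haze is defined on raw data; refusing a contrast-adjusted volume")
  }
  v <- volume$intensities
  nb <- dim(v)[1]; na <- dim(v)[2]; nd <- dim(v)[3]
  prof <- matrix(v, nb * na, nd)  # rows = A-scans in (b, a) order
  hits <- ilm_detect_cpp(prof, k, 1e-4 * max(v))
  depth <- matrix(ifelse(hits < 0, NA_integer_, as.integer(hits)), nb, na)
  surf <- ilm_surface(depth, nd)
  if (lateral_window > 1L) surf <- surface_smooth(surf, lateral_window)
  attr(surf, "volume_failed") <- surf$failure_fraction > max_failure_fraction
  surf
}

#' Median-smooth an ILM surface laterally
#'
#' 2-D median filter across `(b_scan, a_scan)` ignoring failed entries;
#' failed A-scans stay failed (no interpolation). Idempotent on flat
#' surfaces.
#'
#' @param surface an [ilm_surface].
#' @param window odd window size `>= 1`.
#' @return Smoothed [ilm_surface].
#' @export
surface_smooth <- function(surface, window = 5L) {
  stopifnot(inherits(surface, "ilm_surface"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window == 1L) return(surface)
  sm <- median_filter2d_cpp(surface$depth_index, (window - 1L) %/% 2L)
  ilm_surface(sm, surface$n_depth)
}

#' Write / read an ILM surface as CSV
#'
#' Long format `(b_scan, a_scan, depth_index)`; failed A-scans are stored
#' as `-1`.
#'
#' @param surface an [ilm_surface].
#' @param path CSV path.
#' @param n_depth depth extent, needed by `read_ilm_surface()` for
#'   validation.
#' @return `write_ilm_surface()` returns `path` invisibly;
#'   `read_ilm_surface()` returns an [ilm_surface].
#' @export
write_ilm_surface <- function(surface, path) {
  stopifnot(inherits(surface, "ilm_surface"))
  d <- surface$depth_index
  df <- tibble::tibble(
    b_scan = rep(seq_len(nrow(d)), times = ncol(d)),
    a_scan = rep(seq_len(ncol(d)), each = nrow(d)),
    depth_index = ifelse(is.na(as.vector(d)), -1L, as.vector(d))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_ilm_surface
#' @export
read_ilm_surface <- function(path, n_depth) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nb <- max(df$b_scan); na <- max(df$a_scan)
  d <- matrix(NA_integer_, nb, na)
  d[cbind(df$b_scan, df$a_scan)] <-
    ifelse(df$depth_index < 0, NA_integer_, as.integer(df$depth_index))
  ilm_surface(d, n_depth)
}
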