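#' Construct a macular thickness map
#'
#' A per-A-scan layer thickness map over the `(b_scan, a_scan)` raster of a
#' macular volume scan, with the lateral pixel spacings and the fovea centre
#' needed to lay down the ETDRS-style sector grid. B-scan index increasing
#' is taken as inferior; for right eyes (OD) increasing A-scan index is
#' nasal, mirrored for left eyes (OS).
#'
#' @param thickness_um non-negative numeric matrix `(b_scan, a_scan)`, um.
#' @param bscan_spacing_um,ascan_spacing_um pixel spacings, um.
#' @param fovea_center length-2 vector `(b_scan, a_scan)` (may be
#'   fractional); defaults to the raster centre.
#' @param eye `"OD"` or `"OS"` (controls the nasal/temporal orientation).
#' @return Object of class `thickness_map`.
#' @export
thickness_map <- function(thickness_um, bscan_spacing_um, ascan_spacing_um,
                          fovea_center = (dim(thickness_um) + 1) / 2,
                          eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  stopifnot(is.matrix(thickness_um), all(thickness_um >= 0, na.rm = TRUE),
            bscan_spacing_um > 0, ascan_spacing_um > 0)
  if (fovea_center[1] < 1 || fovea_center[1] > nrow(thickness_um) ||
      fovea_center[2] < 1 || fovea_center[2] > ncol(thickness_um)) {
    stop("fovea_center outside map bounds")
  }
  structure(
    list(thickness_um = thickness_um,
         bscan_spacing_um = bscan_spacing_um,
         ascan_spacing_um = ascan_spacing_um,
         fovea_center = fovea_center, eye = eye),
    class = "thickness_map"
  )
}

# per-pixel sector labels for a thickness map; NA outside the grid.
# Radii in mm: centre < 0.5 excluded, inner ring (0.5, 1.11], outer (1.11, 1.7].
sector_labels <- function(map, r_center = 0.5, r_inner = 1.11, r_outer = 1.7) {
  nb <- nrow(map$thickness_um); na_ <- ncol(map$thickness_um)
  dy <- (seq_len(nb) - map$fovea_center[1]) * map$bscan_spacing_um / 1000
  dx <- (seq_len(na_) - map$fovea_center[2]) * map$ascan_spacing_um / 1000
  if (map$eye == "OS") dx <- -dx  # nasal is mirrored in left eyes
  DX <- matrix(dx, nb, na_, byrow = TRUE)
  DY <- matrix(dy, nb, na_)
  r <- sqrt(DX^2 + DY^2)
  ring <- ifelse(r <= r_center | r > r_outer, NA_character_,
                 ifelse(r <= r_inner, "inner", "outer"))
  # quadrants are half-open 90-degree arcs between the 45-degree diagonals
  # (each diagonal belongs to exactly one quadrant), so the four arcs tile
  # the annulus and a 90-degree rotation permutes them exactly
  U <- -DY  # superior direction
  quad <- ifelse(DX >= U & DX > -U, "nasal",
                 ifelse(U > DX & U >= -DX, "superior",
                        ifelse(-DX > U & U >= DX, "temporal", "inferior")))
  ifelse(is.na(ring), NA_character_, paste(ring, quad, sep = "_"))
}

#' ETDRS-grid sector averaging of a thickness map
#'
#' Averages thickness over the 8 sectors of the 1.0 / 2.22 / 3.4 mm grid
#' centred on the fovea, excluding the central 1.0 mm circle: each pixel is
#' assigned by radius to the inner (0.5-1.11 mm) or outer (1.11-1.7 mm)
#' ring and by angle (45-degree diagonals) to the superior, inferior, nasal
#' or temporal quadrant. The grand mean is the unweighted mean of the 8
#' sector means.
#'
#' @param map a [thickness_map()] covering the 3.4 mm circle.
#' @return Object of class `sector_summary`: `sector_means_um` (named,
#'   8 sectors) and `grand_mean_um`.
#' @export
sector_average <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  half_b <- (nrow(map$thickness_um) - 1) / 2 * map$bscan_spacing_um / 1000
  half_a <- (ncol(map$thickness_um) - 1) / 2 * map$ascan_spacing_um / 1000
  db <- (abs(map$fovea_center[1] - c(1, nrow(map$thickness_um)))) *
    map$bscan_spacing_um / 1000
  da <- (abs(map$fovea_center[2] - c(1, ncol(map$thickness_um)))) *
    map$ascan_spacing_um / 1000
  if (min(db) < 1.7 || min(da) < 1.7) {
    stop("the 3.4 mm grid extends beyond the thickness map")
  }
  lab <- sector_labels(map)
  sectors <- as.vector(outer(c("inner", "outer"),
                             c("superior", "inferior", "nasal", "temporal"),
                             paste, sep = "_"))
  means <- vapply(sectors, function(s) {
    px <- map$thickness_um[!is.na(lab) & lab == s]
    if (length(px) == 0L) stop("empty sector: ", s)
    mean(px)
  }, numeric(1))
  structure(
    list(sector_means_um = means, grand_mean_um = mean(means)),
    class = "sector_summary"
  )
}

#' @export
print.sector_summary <- function(x, ...) {
  cat(sprintf("sector_summary: grand mean %.2f um\n", x$grand_mean_um))
  print(round(x$sector_means_um, 2))
  invisible(x)
}

#' Mean peripapillary RNFL thickness on a circular scan
#'
#' Global mean of the per-A-scan thickness measured on a 12-degree circular
#' scan around the optic nerve head, ignoring invalid (`NA` or negative)
#' A-scans.
#'
#' @param circular_scan_thickness numeric vector of per-A-scan thickness, um.
#' @return Mean thickness in um.
#' @export
prnfl_mean <- function(circular_scan_thickness) {
  ok <- is.finite(circular_scan_thickness) & circular_scan_thickness >= 0
  if (!any(ok)) stop("no valid A-scans in circular scan")
  mean(circular_scan_thickness[ok])
}

#' Layer thickness maps from phantom ground truth
#'
#' Converts the boundary depth indices of a phantom's truth sidecar to
#' thickness maps in micrometres (RNFL = `gcl_top - ilm`, GCIPL =
#' `inl_top - gcl_top`, INL = `opl_top - inl_top`, each times the axial
#' spacing), ready for [sector_average()].
#'
#' @param truth a `phantom_truth` from [generate_volume()].
#' @param eye `"OD"` or `"OS"`.
#' @return Named list of [thickness_map()] objects (`rnfl`, `gcipl`, `inl`).
#' @export
truth_thickness_maps <- function(truth, eye = "OD") {
  stopifnot(inherits(truth, "phantom_truth"))
  p <- truth$params
  mk <- function(top, bottom) {
    thickness_map((bottom - top) * p$axial_spacing_um,
                  p$bscan_spacing_um, p$lateral_spacing_um, eye = eye)
  }
  b <- truth$boundaries
  list(
    rnfl = mk(b$ilm, b$gcl_top),
    gcipl = mk(b$gcl_top, b$inl_top),
    inl = mk(b$inl_top, b$opl_top)
  )
}
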