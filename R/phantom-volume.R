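#' Construct a raw OCT volume object
#'
#' A `raw_oct_volume` holds a 3-D non-negative intensity stack indexed
#' `(b_scan, a_scan, depth)`, with the depth axis oriented so that index 1 is
#' the top of the image (vitreous side), plus the acquisition geometry. The
#' `is_contrast_adjusted` flag distinguishes raw device data (on which the
#' vitreous-haze score is defined) from display-transformed data.
#'
#' @param intensities 3-D array `(b_scan, a_scan, depth)` of non-negative
#'   intensities.
#' @param axial_spacing_um axial (depth) pixel spacing in micrometres.
#' @param lateral_spacing_um A-scan spacing within a B-scan, micrometres.
#' @param bscan_spacing_um spacing between adjacent B-scans, micrometres.
#' @param is_contrast_adjusted logical; `TRUE` only for display-transformed
#'   volumes produced by [contrast_adjust()].
#' @return An object of class `raw_oct_volume`.
#' @export
raw_oct_volume <- function(intensities, axial_spacing_um, lateral_spacing_um,
                           bscan_spacing_um = lateral_spacing_um,
                           is_contrast_adjusted = FALSE) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  stopifnot(axial_spacing_um > 0, lateral_spacing_um > 0, bscan_spacing_um > 0)
  structure(
    list(
      intensities = intensities,
      axial_spacing_um = axial_spacing_um,
      lateral_spacing_um = lateral_spacing_um,
      bscan_spacing_um = bscan_spacing_um,
      is_contrast_adjusted = isTRUE(is_contrast_adjusted)
    ),
    class = "raw_oct_volume"
  )
}

#' @export
print.raw_oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "raw_oct_volume: %d B-scans x %d A-scans x %d depth px (%s)\n",
    d[1], d[2], d[3],
    if (x$is_contrast_adjusted) "contrast-adjusted" else "raw"
  ))
  invisible(x)
}

#' @export
dim.raw_oct_volume <- function(x) dim(x$intensities)

#' Default phantom parameters
#'
#' The defaults follow the macular acquisition geometry of a 20 x 20 degree
#' volume scan: 49 B-scans of 512 A-scans each (depth 496 px, ~3.87 um axial
#' spacing). The lateral field is converted at 300 um per degree. The layer
#' stack below the internal limiting membrane (ILM) is piecewise constant
#' (RNFL bright, then GCIPL, INL, outer retina) with narrow high-intensity
#' peaks at the inner/outer segment (IS/OS) junction and the retinal pigment
#' epithelium (RPE), a dark vitreous above the ILM, and a foveal pit rendered
#' as a Gaussian depression of the ILM.
#'
#' @param n_bscans,n_ascans,n_depth volume dimensions (depth must be >= 8).
#' @param ilm_frac,pit_frac,pit_radius_frac ILM base depth, foveal pit depth
#'   and pit radius, as fractions of `n_depth` / lateral field.
#' @param baseline mean vitreous intensity with zero haze.
#' @param haze_level mean intensity added to the vitreous compartment.
#' @param noise_sigma relative standard deviation of the multiplicative
#'   log-normal speckle (mean-one multiplier).
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param gamma display-transform exponent used by [contrast_adjust()].
#' @return Named list of phantom parameters.
#' @export
phantom_params <- function(n_bscans = 49L, n_ascans = 512L, n_depth = 496L,
                           ilm_frac = 0.35, pit_frac = 0.05,
                           pit_radius_frac = 0.15,
                           baseline = 0.05, haze_level = 0.01,
                           noise_sigma = 0.05, read_noise_sd = 0,
                           gamma = 0.5) {
  p <- list(
    n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
    n_depth = as.integer(n_depth),
    ilm_frac = ilm_frac, pit_frac = pit_frac,
    pit_radius_frac = pit_radius_frac,
    baseline = baseline, haze_level = haze_level,
    noise_sigma = noise_sigma, read_noise_sd = read_noise_sd,
    gamma = gamma,
    # fractional layer thicknesses below the ILM
    rnfl_frac = 0.05, gcipl_frac = 0.07, inl_frac = 0.05, outer_frac = 0.12,
    peak_width = 2L,
    layer_intensity = c(
      rnfl = 0.80, gcipl = 0.45, inl = 0.30, outer = 0.15,
      sub_isos = 0.25, choroid = 0.20
    ),
    peak_intensity = 1.0,
    axial_spacing_um = 1920 / n_depth,
    lateral_spacing_um = 6000 / n_ascans,
    bscan_spacing_um = 6000 / n_bscans
  )
  if (p$n_depth < 8L) stop("n_depth must be at least 8")
  stopifnot(p$n_bscans >= 1, p$n_ascans >= 1, p$baseline >= 0,
            p$haze_level >= 0, p$noise_sigma >= 0, p$read_noise_sd >= 0)
  p
}

# Layer boundary depth indices for one A-scan, given its ILM depth.
# Returns named integer vector (ilm, gcl_top, inl_top, opl_top, isos, rpe),
# strictly increasing.
boundaries_from_ilm <- function(ilm, params) {
  d <- params$n_depth
  px <- function(f) max(1L, as.integer(round(f * d)))
  b <- cumsum(c(
    ilm = as.integer(ilm),
    gcl_top = px(params$rnfl_frac),
    inl_top = px(params$gcipl_frac),
    opl_top = px(params$inl_frac),
    isos = px(params$outer_frac),
    rpe = px(0.03) + params$peak_width
  ))
  if (b[["rpe"]] + params$peak_width > d) {
    stop("layer stack exceeds depth range; increase n_depth or raise the ILM")
  }
  b
}

#' Render a single A-scan intensity profile
#'
#' Builds one raw A-scan: a dark vitreous segment (`baseline + haze_level`
#' mean intensity) above the ILM, piecewise-constant layer intensities below
#' it, and narrow high-intensity peaks at the IS/OS junction and the RPE.
#' Noise is a mean-one multiplicative log-normal speckle of relative standard
#' deviation `noise_sigma` plus additive Gaussian read noise, and the result
#' is clipped at zero, so the expected vitreous intensity equals
#' `baseline + haze_level` exactly. Uses the current RNG state.
#'
#' @param boundaries named increasing integer vector of layer-top depth
#'   indices `(ilm, gcl_top, inl_top, opl_top, isos, rpe)`, all within
#'   `[1, n_depth]`.
#' @param params phantom parameter list from [phantom_params()] (supplies
#'   layer intensities, peak shape, baseline and noise defaults).
#' @param haze_level,noise_sigma,read_noise_sd overrides of the
#'   corresponding `params` entries.
#' @param n_depth profile length; defaults to `params$n_depth`.
#' @return Numeric vector of `n_depth` non-negative intensities.
#' @export
generate_ascan_profile <- function(boundaries, params = phantom_params(),
                                   haze_level = params$haze_level,
                                   noise_sigma = params$noise_sigma,
                                   read_noise_sd = params$read_noise_sd,
                                   n_depth = params$n_depth) {
  if (any(diff(boundaries) <= 0)) {
    stop("invalid geometry: layer boundaries must be strictly increasing")
  }
  if (boundaries[1] < 2 || boundaries[length(boundaries)] +
        params$peak_width - 1 > n_depth) {
    stop("invalid geometry: boundaries outside depth range")
  }
  li <- params$layer_intensity
  pw <- params$peak_width
  depth <- seq_len(n_depth)
  prof <- rep(params$baseline + haze_level, n_depth)
  b <- boundaries
  prof[depth >= b[["ilm"]]] <- li[["rnfl"]]
  prof[depth >= b[["gcl_top"]]] <- li[["gcipl"]]
  prof[depth >= b[["inl_top"]]] <- li[["inl"]]
  prof[depth >= b[["opl_top"]]] <- li[["outer"]]
  prof[depth >= b[["isos"]]] <- params$peak_intensity
  prof[depth >= b[["isos"]] + pw] <- li[["sub_isos"]]
  prof[depth >= b[["rpe"]]] <- params$peak_intensity
  prof[depth >= b[["rpe"]] + pw] <- li[["choroid"]]
  apply_phantom_noise(prof, noise_sigma, read_noise_sd)
}

# Mean-one multiplicative log-normal speckle + additive read noise, clip >= 0.
apply_phantom_noise <- function(x, noise_sigma, read_noise_sd) {
  if (noise_sigma > 0) {
    sdlog <- sqrt(log(1 + noise_sigma^2))
    x <- x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
  }
  if (read_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, read_noise_sd)
  }
  pmax(x, 0)
}

#' Generate a synthetic raw OCT volume with known ground truth
#'
#' Renders a full macular volume phantom: a curved (foveal-pit) ILM surface,
#' piecewise-constant retinal layers with IS/OS and RPE peaks, vitreous haze,
#' and speckle noise. The returned truth sidecar records the exact rendered
#' boundary depths, so segmentation and scoring can be validated against
#' ground truth.
#'
#' @param params phantom parameters from [phantom_params()].
#' @param seed integer seed; identical seeds give bit-identical volumes.
#' @return List with elements `volume` ([raw_oct_volume]) and `truth`
#'   (class `phantom_truth`: `ilm_depth` matrix, named list of boundary
#'   matrices, `vitreous_haze_level`, `noise_sigma`).
#' @export
generate_volume <- function(params = phantom_params(), seed = 1L) {
  set.seed(seed)
  nb <- params$n_bscans; na <- params$n_ascans; nd <- params$n_depth

  # ILM surface: base depth plus Gaussian foveal pit centred in the field
  base <- round(params$ilm_frac * nd)
  pit <- params$pit_frac * nd
  bc <- (nb + 1) / 2; ac <- (na + 1) / 2
  rb <- (seq_len(nb) - bc) * params$bscan_spacing_um
  ra <- (seq_len(na) - ac) * params$lateral_spacing_um
  w <- params$pit_radius_frac * 6000
  r2 <- outer(rb^2, ra^2, "+")
  ilm <- matrix(as.integer(round(base + pit * exp(-r2 / (2 * w^2)))), nb, na)
  ilm <- pmax(ilm, max(2L, as.integer(nd / 8) + 1L))

  # boundary matrices share the fixed layer thicknesses of the parameter set
  offs <- boundaries_from_ilm(0L, params)  # offsets relative to ILM
  bnames <- names(offs)
  boundaries <- lapply(offs, function(o) ilm + as.integer(o))
  names(boundaries) <- bnames
  if (max(boundaries$rpe) + params$peak_width - 1 > nd) {
    stop("layer stack exceeds depth range; increase n_depth or lower ilm_frac")
  }

  # vectorized render: overwrite from the vitreous downwards
  li <- params$layer_intensity
  pw <- params$peak_width
  depth_arr <- array(rep(seq_len(nd), each = nb * na), c(nb, na, nd))
  rep3 <- function(m) array(m, c(nb, na, nd))
  vol <- array(params$baseline + params$haze_level, c(nb, na, nd))
  vol[depth_arr >= rep3(boundaries$ilm)] <- li[["rnfl"]]
  vol[depth_arr >= rep3(boundaries$gcl_top)] <- li[["gcipl"]]
  vol[depth_arr >= rep3(boundaries$inl_top)] <- li[["inl"]]
  vol[depth_arr >= rep3(boundaries$opl_top)] <- li[["outer"]]
  vol[depth_arr >= rep3(boundaries$isos)] <- params$peak_intensity
  vol[depth_arr >= rep3(boundaries$isos + pw)] <- li[["sub_isos"]]
  vol[depth_arr >= rep3(boundaries$rpe)] <- params$peak_intensity
  vol[depth_arr >= rep3(boundaries$rpe + pw)] <- li[["choroid"]]

  vol[] <- apply_phantom_noise(as.vector(vol), params$noise_sigma,
                               params$read_noise_sd)

  truth <- structure(
    list(
      ilm_depth = ilm,
      boundaries = boundaries,
      vitreous_haze_level = params$haze_level,
      noise_sigma = params$noise_sigma,
      params = params
    ),
    class = "phantom_truth"
  )
  list(
    volume = raw_oct_volume(vol, params$axial_spacing_um,
                            params$lateral_spacing_um,
                            params$bscan_spacing_um),
    truth = truth
  )
}

#' Apply the display contrast transform to a raw volume
#'
#' Device viewers brighten OCT images for display; relative to the retina,
#' the vitreous signal is artificially increased, which is why haze must be
#' scored on raw data. The transform used here is a max-normalized gamma map
#' `(v / max(v))^gamma` with `gamma < 1` (monotone and concave), after which
#' the volume is flagged `is_contrast_adjusted` and rejected by
#' [segment_ilm()] and [compute_vh()].
#'
#' @param volume a raw [raw_oct_volume].
#' @param gamma exponent in `(0, 1]`; default 0.5.
#' @return The transformed volume, flagged as contrast-adjusted.
#' @export
contrast_adjust <- function(volume, gamma = 0.5) {
  stopifnot(inherits(volume, "raw_oct_volume"))
  if (volume$is_contrast_adjusted) {
    stop("volume is already contrast-adjusted")
  }
  stopifnot(gamma > 0, gamma <= 1)
  v <- volume$intensities
  m <- max(v)
  if (m > 0) v <- (v / m)^gamma
  raw_oct_volume(v, volume$axial_spacing_um, volume$lateral_spacing_um,
                 volume$bscan_spacing_um, is_contrast_adjusted = TRUE)
}

#' Write / read an OCT volume as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per B-scan (rows = depth, top row = vitreous side);
#' intensities are stored divided by `intensity_scale = max(1, max(v))` to
#' fit the unit range, and the sidecar records the scale, geometry and the
#' contrast flag so that `read_oct_volume()` restores the volume exactly.
#'
#' @param volume a [raw_oct_volume].
#' @param path TIFF file path; sidecar is written to `paste0(path, ".json")`.
#' @return `write_oct_volume()` returns `path` invisibly;
#'   `read_oct_volume()` returns a [raw_oct_volume].
#' @export
write_oct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "raw_oct_volume"))
  v <- volume$intensities
  scale <- max(1, max(v))
  pages <- lapply(seq_len(dim(v)[1]), function(b) t(v[b, , ]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    n_bscans = dim(v)[1], n_ascans = dim(v)[2], n_depth = dim(v)[3],
    axial_spacing_um = volume$axial_spacing_um,
    lateral_spacing_um = volume$lateral_spacing_um,
    bscan_spacing_um = volume$bscan_spacing_um,
    is_contrast_adjusted = volume$is_contrast_adjusted,
    intensity_scale = scale,
    depth_orientation = "index 1 = vitreous side"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- array(0, c(meta$n_bscans, meta$n_ascans, meta$n_depth))
  for (b in seq_along(pages)) v[b, , ] <- t(pages[[b]]) * meta$intensity_scale
  raw_oct_volume(v, meta$axial_spacing_um, meta$lateral_spacing_um,
                 meta$bscan_spacing_um,
                 is_contrast_adjusted = meta$is_contrast_adjusted)
}

#' Write phantom ground truth as CSV
#'
#' Long-format table with one row per A-scan and one column per layer
#' boundary depth index.
#'
#' @param truth `phantom_truth` object from [generate_volume()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  nb <- nrow(truth$ilm_depth); na <- ncol(truth$ilm_depth)
  df <- tibble::tibble(
    b_scan = rep(seq_len(nb), times = na),
    a_scan = rep(seq_len(na), each = nb)
  )
  for (nm in names(truth$boundaries)) df[[nm]] <- as.vector(truth$boundaries[[nm]])
  readr::write_csv(df, path)
  invisible(path)
}
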