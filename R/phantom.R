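#' Specification of the digital cardiac phantom
#'
#' Describes a desk-scale dynamic cardiac PET phantom: an ellipsoidal left
#' ventricular (LV) blood cavity surrounded by a myocardial shell of constant
#' wall thickness, an adjacent right ventricular (RV) blood cavity, and
#' background tissue, together with per-region kinetic parameters, the
#' arterial bolus shape, PSF blur and the noise level. World coordinates are
#' mm with voxel `(0,0,0)` centred at the origin; the heart defaults to the
#' grid centre.
#'
#' All geometry must fit inside the grid with at least `search_margin_mm` of
#' clearance so that simulated motion up to the registration search radius
#' never pushes the heart off the grid.
#'
#' @param grid_shape integer length-3 voxel counts (default `c(48,48,48)`).
#' @param spacing_mm voxel size in mm (default 2 mm isotropic).
#' @param lv_center_mm LV centre in mm; default grid centre.
#' @param lv_radii_mm semi-axes of the LV cavity ellipsoid (mm). A radius of 0
#'   gives an empty cavity; the myocardial shell is then a filled ellipsoid.
#' @param wall_mm myocardial wall thickness (mm), added to each cavity
#'   semi-axis to form the epicardial ellipsoid; must be positive.
#' @param rv_offset_mm RV cavity centre offset from the LV centre (mm).
#' @param rv_radii_mm semi-axes of the RV cavity ellipsoid (mm).
#' @param region_kinetics named list mapping `myocardium` and `background` to
#'   `c(K1, k2, fv)` (ml/g/min, 1/min, unitless). Blood cavities carry the
#'   input function itself.
#' @param segment_k1_scale per-segment multipliers on myocardial K1 giving
#'   mild regional heterogeneity; length `n_segments`.
#' @param n_segments number of angular myocardial segments (default 6).
#' @param bolus list with `amplitude`, `delay_s`, `peak_s`, `shape`,
#'   `recirc_frac` for [make_input_function()].
#' @param psf_fwhm_mm reconstruction PSF full-width-half-max (mm).
#' @param noise_scale nonnegative scalar; Gaussian noise variance is
#'   `noise_scale * intensity` (a reconstruction-domain surrogate for Poisson
#'   counting noise).
#' @param search_margin_mm required clearance between heart and grid edge.
#' @param seed default seed for rendering noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing_mm = c(2, 2, 2),
                         lv_center_mm = NULL,
                         lv_radii_mm = c(9, 9, 12),
                         wall_mm = 7,
                         rv_offset_mm = c(-14, 0, 0),
                         rv_radii_mm = c(6, 8, 10),
                         region_kinetics = list(
                           myocardium = c(K1 = 0.9, k2 = 0.12, fv = 0.30),
                           background = c(K1 = 0.08, k2 = 0.05, fv = 0.05)),
                         segment_k1_scale = c(1, 0.95, 1.05, 0.9, 1.1, 1),
                         n_segments = 6L,
                         bolus = list(amplitude = 100, delay_s = 10,
                                      peak_s = 25, shape = 3,
                                      recirc_frac = 0.12),
                         psf_fwhm_mm = 6,
                         noise_scale = 0,
                         search_margin_mm = 25,
                         seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stop_if(length(grid_shape) != 3L || any(grid_shape < 4L), "grid_shape must be 3 values >= 4")
  stop_if(length(spacing_mm) != 3L || any(spacing_mm <= 0), "spacing_mm must be positive")
  stop_if(wall_mm <= 0, "wall_mm must be positive")
  stop_if(any(lv_radii_mm < 0) || any(rv_radii_mm < 0), "radii must be nonnegative")
  stop_if(noise_scale < 0, "noise_scale must be nonnegative")
  stop_if(psf_fwhm_mm < 0, "psf_fwhm_mm must be nonnegative")
  for (nm in c("myocardium", "background")) {
    kk <- region_kinetics[[nm]]
    stop_if(is.null(kk) || length(kk) != 3L, "region_kinetics$", nm, " must be c(K1, k2, fv)")
    stop_if(kk[3] < 0 || kk[3] > 1, "fv for ", nm, " must be in [0, 1]")
    stop_if(kk[1] < 0 || kk[2] < 0, "K1 and k2 for ", nm, " must be nonnegative")
  }
  stop_if(length(segment_k1_scale) != n_segments,
          "segment_k1_scale must have length n_segments")
  extent <- (grid_shape - 1) * spacing_mm
  if (is.null(lv_center_mm)) lv_center_mm <- extent / 2
  spec <- structure(list(
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    lv_center_mm = as.numeric(lv_center_mm),
    lv_radii_mm = as.numeric(lv_radii_mm), wall_mm = wall_mm,
    rv_offset_mm = as.numeric(rv_offset_mm),
    rv_radii_mm = as.numeric(rv_radii_mm),
    region_kinetics = region_kinetics,
    segment_k1_scale = as.numeric(segment_k1_scale),
    n_segments = as.integer(n_segments),
    bolus = bolus, psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale,
    search_margin_mm = search_margin_mm, seed = seed),
    class = "phantom_spec")
  axn <- c("x", "y", "z")
  check_fit <- function(center, radii, what) {
    lo <- center - radii - spec$search_margin_mm
    hi <- center + radii + spec$search_margin_mm
    bad <- which(lo < 0 | hi > extent)
    stop_if(length(bad) > 0,
            what, " radius ", radii[bad[1]], " mm along ", axn[bad[1]],
            " does not fit in the grid with a ", spec$search_margin_mm,
            " mm margin")
  }
  check_fit(spec$lv_center_mm, spec$lv_radii_mm + wall_mm, "epicardial")
  check_fit(spec$lv_center_mm + spec$rv_offset_mm, spec$rv_radii_mm, "RV")
  spec
}

# Squared normalised ellipsoid distance; radius 0 along any axis makes the
# ellipsoid empty (infinite distance) except exactly at the centre plane.
ellipsoid_q <- function(cx, cy, cz, center, radii) {
  q <- array(0, dim = dim(cx))
  for (ax in 1:3) {
    d <- switch(ax, cx, cy, cz) - center[ax]
    if (radii[ax] > 0) q <- q + (d / radii[ax])^2
    else q <- q + ifelse(d == 0, 0, Inf)
  }
  q
}

#' Rasterise the phantom geometry
#'
#' Assigns every voxel to exactly one of background (0), LV cavity (1),
#' myocardium (2) or RV cavity (3), and splits the myocardium into angular
#' segments about the LV long (z) axis.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `pet_phantom`: list with `labels` (integer 3D
#'   array), `masks` (named list of logical arrays: `background`, `lv_cavity`,
#'   `myocardium`, `rv_cavity`), `segments` (integer array, 0 outside the
#'   myocardium, 1..n inside), and the `spec`.
#' @examples
#' ph <- build_phantom(phantom_spec(grid_shape = c(24, 24, 24),
#'                                  spacing_mm = c(4, 4, 4)))
#' table(ph$labels)
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sx <- spec$spacing_mm
  cx <- array(rep((0:(d[1] - 1)) * sx[1], times = d[2] * d[3]), dim = d)
  cy <- array(rep(rep((0:(d[2] - 1)) * sx[2], each = d[1]), times = d[3]), dim = d)
  cz <- array(rep((0:(d[3] - 1)) * sx[3], each = d[1] * d[2]), dim = d)
  q_cav <- ellipsoid_q(cx, cy, cz, spec$lv_center_mm, spec$lv_radii_mm)
  q_epi <- ellipsoid_q(cx, cy, cz, spec$lv_center_mm, spec$lv_radii_mm + spec$wall_mm)
  q_rv <- ellipsoid_q(cx, cy, cz, spec$lv_center_mm + spec$rv_offset_mm, spec$rv_radii_mm)
  lv <- q_cav <= 1
  myo <- (q_epi <= 1) & !lv
  rv <- (q_rv <= 1) & !lv & !myo
  bg <- !(lv | myo | rv)
  labels <- array(0L, dim = d)
  labels[lv] <- 1L; labels[myo] <- 2L; labels[rv] <- 3L
  ang <- atan2(cy - spec$lv_center_mm[2], cx - spec$lv_center_mm[1])
  seg <- 1L + pmin(spec$n_segments - 1L,
                   as.integer(floor((ang + pi) / (2 * pi / spec$n_segments))))
  segments <- array(0L, dim = d)
  segments[myo] <- seg[myo]
  structure(list(labels = labels,
                 masks = list(background = bg, lv_cavity = lv,
                              myocardium = myo, rv_cavity = rv),
                 segments = segments, spec = spec),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("<pet_phantom> %s voxels; LV cavity %d, myocardium %d, RV %d voxels, %d segments\n",
              paste(x$spec$grid_shape, collapse = "x"),
              sum(x$masks$lv_cavity), sum(x$masks$myocardium),
              sum(x$masks$rv_cavity), x$spec$n_segments))
  invisible(x)
}

#' A time-activity curve
#'
#' @param t_mid_s ascending mid-frame times (s).
#' @param activity mean activity per time point (arbitrary units).
#' @return Object of class `tac` with fields `t_mid_s`, `activity`.
#' @export
tac <- function(t_mid_s, activity) {
  t_mid_s <- as.numeric(t_mid_s); activity <- as.numeric(activity)
  stop_if(length(t_mid_s) != length(activity), "t_mid_s and activity lengths differ")
  stop_if(is.unsorted(t_mid_s, strictly = TRUE), "t_mid_s must be strictly ascending")
  structure(list(t_mid_s = t_mid_s, activity = activity), class = "tac")
}

#' Gamma-variate arterial input function
#'
#' Blood-pool activity after a venous bolus: zero before the bolus delay, a
#' single gamma-variate first pass peaking `peak_s` seconds after arrival,
#' plus an optional slow recirculation tail. Shape follows
#' `((t-d)/p)^a * exp(a * (1 - (t-d)/p))`, normalised so the first-pass peak
#' equals `amplitude`.
#'
#' @param t_mid_s ascending evaluation times (s).
#' @param bolus list with `amplitude`, `delay_s`, `peak_s`, `shape` (> 0) and
#'   `recirc_frac` (fraction of the peak carried by the recirculation tail).
#' @return a [tac].
#' @export
make_input_function <- function(t_mid_s, bolus = phantom_spec()$bolus) {
  stop_if(is.unsorted(t_mid_s, strictly = TRUE), "t_mid_s must be ascending")
  stop_if(is.null(bolus$shape) || bolus$shape <= 0, "bolus shape must be positive")
  stop_if(is.null(bolus$peak_s) || bolus$peak_s <= 0, "bolus peak_s must be positive")
  a <- bolus$amplitude
  d <- bolus$delay_s %||% 0
  p <- bolus$peak_s
  al <- bolus$shape
  rc <- bolus$recirc_frac %||% 0
  td <- pmax(0, t_mid_s - d)
  g <- ifelse(t_mid_s > d, (td / p)^al * exp(al * (1 - td / p)), 0)
  tail <- ifelse(t_mid_s > d, rc * (1 - exp(-td / 60)) * exp(-td / 600), 0)
  tac(t_mid_s, a * (g + tail))
}

#' Render a dynamic series from the phantom
#'
#' Each frame paints every region (and, within the myocardium, every
#' segment) with its time-activity value, applies a Gaussian PSF and adds
#' Gaussian noise with variance proportional to local intensity.
#'
#' @param phantom a [build_phantom()] result.
#' @param tacs named list of per-region activity vectors, one value per frame:
#'   entries `background`, `lv_cavity`, `rv_cavity`, and `myocardium`. The
#'   myocardium entry may be a single vector or an `n_frames x n_segments`
#'   matrix for per-segment kinetics.
#' @param schedule a [frame_schedule]; lengths must match the TAC vectors.
#' @param psf_fwhm_mm,noise_scale,seed override the values in the phantom
#'   spec.
#' @return a [dynamic_series].
#' @export
render_series <- function(phantom, tacs, schedule,
                          psf_fwhm_mm = NULL, noise_scale = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "pet_phantom"))
  spec <- phantom$spec
  psf_fwhm_mm <- psf_fwhm_mm %||% spec$psf_fwhm_mm
  noise_scale <- noise_scale %||% spec$noise_scale
  seed <- seed %||% spec$seed
  nf <- length(schedule)
  myo <- tacs$myocardium
  if (is.matrix(myo)) {
    stop_if(nrow(myo) != nf, "myocardium TAC has ", nrow(myo),
            " frames, schedule has ", nf)
    stop_if(ncol(myo) != spec$n_segments, "myocardium TAC matrix needs one column per segment")
  } else {
    stop_if(length(myo) != nf, "myocardium TAC has ", length(myo),
            " frames, schedule has ", nf)
  }
  for (nm in c("background", "lv_cavity", "rv_cavity")) {
    stop_if(length(tacs[[nm]]) != nf, nm, " TAC has ", length(tacs[[nm]]),
            " values, schedule has ", nf, " frames")
  }
  d <- spec$grid_shape
  sigma_vox <- if (psf_fwhm_mm > 0) (psf_fwhm_mm / 2.354820045) / spec$spacing_mm else c(0, 0, 0)
  seg_masks <- lapply(seq_len(spec$n_segments), function(s) phantom$segments == s)
  out <- array(0, dim = c(d, nf))
  with_seed(seed, {
    for (i in seq_len(nf)) {
      vol <- array(0, dim = d)
      vol[phantom$masks$background] <- tacs$background[i]
      vol[phantom$masks$lv_cavity] <- tacs$lv_cavity[i]
      vol[phantom$masks$rv_cavity] <- tacs$rv_cavity[i]
      if (is.matrix(myo)) {
        for (s in seq_len(spec$n_segments)) vol[seg_masks[[s]]] <- myo[i, s]
      } else {
        vol[phantom$masks$myocardium] <- myo[i]
      }
      if (any(sigma_vox > 0)) vol <- gauss_blur_3d(vol, sigma_vox)
      if (noise_scale > 0) {
        vol <- vol + stats::rnorm(length(vol)) * sqrt(noise_scale * pmax(vol, 0))
      }
      out[, , , i] <- vol
    }
  })
  dynamic_series(out, spec$spacing_mm, schedule)
}
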