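#' Summed-late-frame alignment reference
#'
#' All frames of a dynamic scan are aligned to a single reference volume
#' built by summing the late frames, by default those starting at or after
#' two minutes, when tracer uptake is stable and patient motion is least.
#'
#' @param series a [dynamic_series].
#' @param cutoff_s frames with `start_s >= cutoff_s` are summed (default 120).
#' @return Object of class `reference_volume`: list with `volume` (3D array),
#'   `spacing_mm`, `cutoff_s`.
#' @export
build_reference <- function(series, cutoff_s = 120) {
  stopifnot(inherits(series, "dynamic_series"))
  stop_if(cutoff_s < 0, "cutoff_s must be >= 0")
  idx <- which(series$schedule$start_s >= cutoff_s)
  stop_if(length(idx) == 0, "no frames start at or after ", cutoff_s, " s")
  d <- dim(series$voxels)[1:3]
  vol <- array(0, dim = d)
  for (i in idx) vol <- vol + series$voxels[, , , i]
  structure(list(volume = vol, spacing_mm = series$spacing_mm,
                 cutoff_s = cutoff_s, n_frames = length(idx)),
            class = "reference_volume")
}

# Intensity centroid (mm) of the positive part of a volume.
intensity_centroid <- function(vol, spacing_mm) {
  v <- pmax(vol, 0)
  s <- sum(v)
  if (s <= 0) return(rep(NA_real_, 3))
  d <- dim(vol)
  w1 <- apply(v, 1, sum); w2 <- apply(v, 2, sum); w3 <- apply(v, 3, sum)
  c(sum((0:(d[1] - 1)) * spacing_mm[1] * w1),
    sum((0:(d[2] - 1)) * spacing_mm[2] * w2),
    sum((0:(d[3] - 1)) * spacing_mm[3] * w3)) / s
}

# Robust [0,1] normalisation by the 99.9th percentile, clipped.
normalize_volume <- function(vol) {
  q <- stats::quantile(vol, 0.999, names = FALSE)
  if (q <= 0) q <- max(vol)
  if (q <= 0) return(vol * 0)
  pmin(pmax(vol / q, 0), 1)
}

#' Preprocess a moving/reference volume pair for the regressor
#'
#' Both volumes are resampled onto a common isotropic cubic grid of
#' `config$grid` voxels spanning the original field of view, centred on the
#' intensity centroid of the reference, then each is scaled to `[0, 1]` by
#' its own robust maximum (99.9th percentile, clipped). Normalising each
#' volume separately makes the network invariant to global intensity scale,
#' which varies by orders of magnitude across dynamic frames.
#'
#' @param frame 3D array, the moving frame.
#' @param reference 3D array (or [build_reference()] result).
#' @param spacing_mm voxel spacing of both inputs.
#' @param config a [moco_config()]; only `grid` is used here.
#' @return list with `mov`, `ref` (3D arrays `grid^3`), `out_spacing_mm` and
#'   `origin_mm` of the resampled grid.
#' @export
preprocess_pair <- function(frame, reference, spacing_mm, config = moco_config()) {
  if (inherits(reference, "reference_volume")) reference <- reference$volume
  stop_if(!all(dim(frame) == dim(reference)), "frame and reference shapes differ")
  d <- dim(frame)
  g <- config$grid
  cen <- intensity_centroid(reference, spacing_mm)
  stop_if(any(is.na(cen)), "reference volume is empty (all-zero)")
  out_spacing <- d * spacing_mm / g
  origin <- cen - (g - 1) / 2 * out_spacing
  rs <- function(vol) {
    array(resample_volume_cpp(as.numeric(vol), d, spacing_mm,
                              rep(g, 3L), out_spacing, origin),
          dim = rep(g, 3L))
  }
  list(mov = normalize_volume(rs(frame)), ref = normalize_volume(rs(reference)),
       out_spacing_mm = out_spacing, origin_mm = origin)
}
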