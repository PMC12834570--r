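#' Exhaustive-search rigid translation registration
#'
#' Deterministic frame-to-reference registration: the correction maximising
#' (optionally masked) normalized cross-correlation with the reference over
#' an integer lattice of millimetre steps within `+/- search_radius_mm` per
#' axis. A coarse-to-fine schedule (4 -> 2 -> `step_mm`) keeps the search
#' tractable; ties are broken by smallest Euclidean norm, then
#' lexicographically on `(tx, ty, tz)`.
#'
#' This intensity-based search stands in for contour-model-based clinical
#' automatic motion correction: the `mask` slot accepts a myocardial
#' segmentation to approximate contour weighting.
#'
#' @param frame 3D array, the moving frame.
#' @param reference 3D array or [build_reference()] result.
#' @param spacing_mm voxel spacing (mm).
#' @param mask optional logical array; NCC is evaluated over these voxels
#'   only (default: the whole grid).
#' @param search_radius_mm half-width of the search cube (default 25 mm).
#' @param step_mm finest step (default 1 mm).
#' @param coarse_to_fine use the 4 -> 2 -> step schedule (default) or a
#'   single exhaustive pass at `step_mm`.
#' @return list with `translation_mm` (the correction, length 3), `metric`
#'   (NCC at the optimum).
#' @export
register_translation <- function(frame, reference, spacing_mm,
                                 mask = NULL, search_radius_mm = 25,
                                 step_mm = 1, coarse_to_fine = TRUE) {
  if (inherits(reference, "reference_volume")) reference <- reference$volume
  stop_if(!all(dim(frame) == dim(reference)), "frame and reference shapes differ")
  stop_if(step_mm <= 0 || search_radius_mm < step_mm,
          "need search_radius_mm >= step_mm > 0")
  stop_if(stats::var(as.numeric(frame)) == 0,
          "constant (zero-variance) frame: NCC undefined")
  d <- dim(frame)
  mask_idx <- if (is.null(mask)) seq_len(prod(d)) - 1L else which(mask) - 1L
  stop_if(length(mask_idx) < 2, "mask selects fewer than 2 voxels")
  fr <- as.numeric(frame); rf <- as.numeric(reference)
  score_at <- function(off_mm) {
    cand <- sweep(off_mm, 2, spacing_mm, "/")
    s <- ncc_search_cpp(fr, rf, d, mask_idx, cand)
    s[is.na(s)] <- -Inf
    s
  }
  pick <- function(off_mm, scores) {
    best <- max(scores)
    tied <- which(scores >= best - 1e-12)
    nrm <- rowSums(off_mm[tied, , drop = FALSE]^2)
    tied <- tied[order(nrm, off_mm[tied, 1], off_mm[tied, 2], off_mm[tied, 3])]
    list(mm = off_mm[tied[1], ], metric = scores[tied[1]])
  }
  grid_mm <- function(center, half, step) {
    ax <- lapply(1:3, function(a) center[a] + seq(-half, half, by = step))
    as.matrix(expand.grid(tx = ax[[1]], ty = ax[[2]], tz = ax[[3]]))
  }
  if (!coarse_to_fine) {
    off <- grid_mm(c(0, 0, 0), floor(search_radius_mm / step_mm) * step_mm, step_mm)
    res <- pick(off, score_at(off))
  } else {
    steps <- c(4, 2, step_mm)
    steps <- steps[steps >= step_mm]
    if (steps[length(steps)] != step_mm) steps <- c(steps, step_mm)
    center <- c(0, 0, 0)
    res <- NULL
    for (i in seq_along(steps)) {
      st <- steps[i]
      half <- if (i == 1L) floor(search_radius_mm / st) * st else steps[i - 1]
      off <- grid_mm(center, half, st)
      res <- pick(off, score_at(off))
      center <- res$mm
    }
  }
  list(translation_mm = as.numeric(res$mm), metric = res$metric)
}

#' Classical motion correction of a dynamic series
#'
#' Registers every frame to the summed-late-frame reference with
#' [register_translation()] and applies the corrections. Very-low-count
#' frames (total activity below `skip_fraction` of the median frame total)
#' are skipped with zero correction, as are frames where registration fails;
#' both are flagged.
#'
#' @param series a [dynamic_series].
#' @param cutoff_s reference cutoff (default 120 s).
#' @param mask optional logical array passed to the registration.
#' @param search_radius_mm,step_mm,coarse_to_fine search parameters.
#' @param skip_fraction low-count skip threshold (default 0.02).
#' @param interpolation resampling used when applying corrections.
#' @return list with `trace` (a [motion_trace]), `corrected` (a
#'   [dynamic_series]), `flags` (character per frame: `"ok"`, `"low_count"`
#'   or `"failed"`), `metric` (per-frame NCC, NA when skipped).
#' @export
correct_series_classic <- function(series, cutoff_s = 120, mask = NULL,
                                   search_radius_mm = 25, step_mm = 1,
                                   coarse_to_fine = TRUE,
                                   skip_fraction = 0.02,
                                   interpolation = "trilinear") {
  stopifnot(inherits(series, "dynamic_series"))
  ref <- build_reference(series, cutoff_s)
  nf <- n_frames(series)
  totals <- frame_totals(series)
  thresh <- skip_fraction * stats::median(totals)
  tr <- matrix(0, nf, 3)
  flags <- character(nf)
  metric <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    if (totals[i] < thresh) {
      flags[i] <- "low_count"
      next
    }
    res <- tryCatch(
      register_translation(get_frame(series, i), ref, series$spacing_mm,
                           mask = mask, search_radius_mm = search_radius_mm,
                           step_mm = step_mm, coarse_to_fine = coarse_to_fine),
      error = function(e) NULL)
    if (is.null(res)) {
      flags[i] <- "failed"
    } else {
      tr[i, ] <- res$translation_mm
      metric[i] <- res$metric
      flags[i] <- "ok"
    }
  }
  trace <- motion_trace(tr, max_mm = max(25, search_radius_mm))
  corrected <- correct_series(series, trace, interpolation)
  list(trace = trace, corrected = corrected, flags = flags, metric = metric)
}
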