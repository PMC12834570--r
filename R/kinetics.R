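#' One-tissue compartment model tissue curve
#'
#' The two-compartment (one-tissue) kinetic model linking the arterial input
#' to the tissue time-activity curve:
#' `C_t(t) = (1 - fv) * K1 * int_0^t exp(-k2 (t - tau)) C_a(tau) dtau + fv * C_a(t)`.
#' The convolution integral is evaluated by an exact-trapezoid recursion on
#' the TAC time grid; before the first sample the input is taken to hold its
#' first sampled value (zero for any bolus arriving after the first frame),
#' which keeps the rule second-order accurate from t = 0.
#'
#' @param input a [tac], the blood-pool input function.
#' @param K1 uptake rate (ml/g/min).
#' @param k2 washout rate (1/min).
#' @param fv fractional blood volume (0..1).
#' @return a [tac] on the same time grid. Note rate units are per minute
#'   while TAC times are seconds; the conversion is internal.
#' @export
model_tac <- function(input, K1, k2, fv) {
  stopifnot(inherits(input, "tac"))
  stop_if(is.unsorted(input$t_mid_s, strictly = TRUE), "unsorted times")
  stop_if(K1 < 0 || k2 < 0, "K1 and k2 must be nonnegative")
  stop_if(fv < 0 || fv > 1, "fv must be in [0, 1]")
  t_min <- input$t_mid_s / 60   # rates are per minute
  ca <- input$activity
  n <- length(t_min)
  conv <- numeric(n)
  # leading segment [0, t1]: input held constant at its first sample
  conv[1] <- if (k2 > 0) ca[1] * (1 - exp(-k2 * t_min[1])) / k2
             else ca[1] * t_min[1]
  # trapezoidal convolution with exp(-k2 t), exact recursion on the grid
  acc <- conv[1]
  for (i in seq_len(n)[-1]) {
    dt <- t_min[i] - t_min[i - 1]
    ek <- exp(-k2 * dt)
    acc <- acc * ek + dt / 2 * (ca[i] + ek * ca[i - 1])
    conv[i] <- acc
  }
  tac(input$t_mid_s, (1 - fv) * K1 * conv + fv * ca)
}

#' Extract a regional time-activity curve
#'
#' Per-frame mean intensity over a voxel mask; times are mid-frame.
#'
#' @param series a [dynamic_series].
#' @param mask logical array matching the spatial grid.
#' @return a [tac].
#' @export
extract_tac <- function(series, mask) {
  stopifnot(inherits(series, "dynamic_series"))
  stop_if(!all(dim(mask) == dim(series$voxels)[1:3]), "mask shape mismatch")
  idx <- which(mask)
  stop_if(length(idx) == 0, "empty mask")
  nf <- n_frames(series)
  act <- vapply(seq_len(nf), function(i) mean(series$voxels[, , , i][idx]), 0)
  tac(frame_mid_times(series$schedule), act)
}

#' Fit the one-tissue compartment model
#'
#' Weighted least squares over `(K1, k2, fv)` by bounded quasi-Newton
#' optimisation (`L-BFGS-B`) with multistart: a few fixed physiological
#' starting points plus seeded random restarts; the best residual sum of
#' squares wins. Weights default to frame durations.
#'
#' @param blood a [tac], the arterial input.
#' @param tissue a [tac] on the same time grid.
#' @param weights nonnegative per-frame weights (default: equal).
#' @param lower,upper bounds on `(K1, k2, fv)`.
#' @param n_starts number of starts (default 5).
#' @param seed seed for the random restarts.
#' @return Object of class `kinetic_fit` with elements `K1`, `k2`, `fv`,
#'   `rss`, `converged`, `degenerate`, plus data for the methods
#'   (`coef`, `predict`, `residuals`, `print`, `summary`).
#' @examples
#' t_mid <- seq(5, 595, by = 10)
#' blood <- make_input_function(t_mid)
#' tissue <- model_tac(blood, K1 = 0.8, k2 = 0.12, fv = 0.3)
#' coef(fit_one_tissue(blood, tissue, seed = 1))
#' @export
fit_one_tissue <- function(blood, tissue, weights = NULL,
                           lower = c(0, 0, 0), upper = c(8, 8, 1),
                           n_starts = 5L, seed = 1L) {
  stopifnot(inherits(blood, "tac"), inherits(tissue, "tac"))
  stop_if(length(blood$t_mid_s) != length(tissue$t_mid_s) ||
            any(abs(blood$t_mid_s - tissue$t_mid_s) > 1e-9),
          "blood and tissue TACs must share one time grid")
  if (is.null(weights)) weights <- rep(1, length(blood$t_mid_s))
  stop_if(any(weights < 0), "weights must be nonnegative")
  obs <- tissue$activity
  base <- list(blood = blood, tissue = tissue, weights = weights)
  if (max(abs(obs)) <= 1e-12 * max(abs(blood$activity), 1e-300)) {
    fit <- structure(c(base, list(K1 = 0, k2 = 0, fv = 0, rss = sum(weights * obs^2),
                                  converged = TRUE, degenerate = TRUE)),
                     class = "kinetic_fit")
    return(fit)
  }
  objective <- function(par) {
    m <- model_tac(blood, par[1], par[2], par[3])$activity
    sum(weights * (m - obs)^2)
  }
  starts <- list(c(0.5, 0.1, 0.1), c(1.0, 0.3, 0.3), c(2.0, 0.6, 0.2))
  extra <- max(0L, n_starts - length(starts))
  if (extra > 0) {
    rnd <- with_seed(seed, matrix(stats::runif(extra * 3), extra, 3))
    for (i in seq_len(extra)) {
      starts[[length(starts) + 1L]] <-
        c(0.1 + 2.9 * rnd[i, 1], 0.01 + 0.99 * rnd[i, 2], 0.6 * rnd[i, 3])
    }
  }
  best <- NULL
  for (st in starts[seq_len(min(n_starts, length(starts)))]) {
    op <- tryCatch(
      stats::optim(pmin(pmax(st, lower), upper), objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 1e3,
                                  ndeps = rep(1e-6, 3))),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  stop_if(is.null(best), "all optimisation starts failed")
  structure(c(base, list(K1 = best$par[1], k2 = best$par[2], fv = best$par[3],
                         rss = best$value, converged = best$convergence == 0,
                         degenerate = FALSE)),
            class = "kinetic_fit")
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(K1 = object$K1, k2 = object$k2, fv = object$fv)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  input <- newdata %||% object$blood
  model_tac(input, object$K1, object$k2, object$fv)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$tissue$activity - predict(object)$activity
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> K1 = %.3f ml/g/min, k2 = %.3f /min, fv = %.3f (rss %.4g%s%s)\n",
              x$K1, x$k2, x$fv, x$rss,
              if (x$converged) "" else ", not converged",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  r <- residuals(object)
  cat(sprintf("One-tissue compartment fit on %d frames\n", length(r)))
  print(object)
  cat(sprintf("  weighted RMS residual: %.4g\n",
              sqrt(sum(object$weights * r^2) / sum(object$weights))))
  invisible(object)
}

#' Simplified residual-activity correction
#'
#' Same-day rest/stress protocols leave tracer from the rest injection in
#' the field at stress time. This subtracts the (optionally
#' decay-extrapolated) rest-study late-frame mean image from every stress
#' frame; negatives are retained.
#'
#' @param stress a [dynamic_series].
#' @param rest_tail 3D array: mean of the rest study's late frames (see
#'   [rest_tail_image()]); `NULL` passes the series through with a warning.
#' @param factor extrapolation factor applied to the tail (default 1).
#' @return a [dynamic_series].
#' @export
residual_activity_correct <- function(stress, rest_tail, factor = 1) {
  stopifnot(inherits(stress, "dynamic_series"))
  if (is.null(rest_tail)) {
    warning("no rest tail image supplied; stress series returned uncorrected")
    return(stress)
  }
  stop_if(!all(dim(rest_tail) == dim(stress$voxels)[1:3]),
          "rest tail image grid does not match the stress series")
  out <- stress$voxels
  for (i in seq_len(n_frames(stress))) {
    out[, , , i] <- out[, , , i] - factor * rest_tail
  }
  dynamic_series(out, stress$spacing_mm, stress$schedule)
}

#' Mean late-frame image of a rest study
#'
#' @param rest a [dynamic_series].
#' @param cutoff_s frames starting at or after this time are averaged.
#' @return 3D array.
#' @export
rest_tail_image <- function(rest, cutoff_s = 120) {
  ref <- build_reference(rest, cutoff_s)
  ref$volume / ref$n_frames
}

#' Segmental flow summary
#'
#' Computes per-segment myocardial blood flow (MBF, reported as the fitted
#' uptake rate K1, optionally passed through a user-supplied extraction
#' function), flow reserve (MFR = stress / rest), and the minimal segmental
#' stress MBF and MFR used as diagnostic scores.
#'
#' @param rest_fits,stress_fits named lists of [fit_one_tissue()] results,
#'   one per segment (same names and order).
#' @param extraction optional function mapping K1 to MBF (default identity).
#' @return Object of class `flow_result`: data.frame with columns `segment`,
#'   `rest_mbf`, `stress_mbf`, `mfr` plus attributes
#'   `min_segmental_stress_mbf` and `min_segmental_mfr`. Segments with zero
#'   rest flow get `NA` MFR and are excluded from the MFR minimum.
#' @export
flow_summary <- function(rest_fits, stress_fits, extraction = identity) {
  stop_if(length(rest_fits) != length(stress_fits),
          "rest and stress segment sets differ")
  segs <- names(rest_fits) %||% as.character(seq_along(rest_fits))
  rest_mbf <- vapply(rest_fits, function(f) extraction(f$K1), 0)
  stress_mbf <- vapply(stress_fits, function(f) extraction(f$K1), 0)
  mfr <- ifelse(rest_mbf > 0, stress_mbf / rest_mbf, NA_real_)
  if (any(is.na(mfr)))
    warning("zero rest MBF in segment(s) ",
            paste(segs[is.na(mfr)], collapse = ", "),
            "; excluded from the MFR minimum")
  out <- data.frame(segment = segs, rest_mbf = rest_mbf,
                    stress_mbf = stress_mbf, mfr = mfr, row.names = NULL)
  attr(out, "min_segmental_stress_mbf") <- min(stress_mbf)
  attr(out, "min_segmental_mfr") <- if (all(is.na(mfr))) NA_real_ else min(mfr, na.rm = TRUE)
  class(out) <- c("flow_result", "data.frame")
  out
}

#' @export
print.flow_result <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("min segmental stress MBF: %.3f   min segmental MFR: %.3f\n",
              attr(x, "min_segmental_stress_mbf"), attr(x, "min_segmental_mfr")))
  invisible(x)
}

# Morphological erosion of a logical mask by k voxels (6-neighbourhood).
erode_mask <- function(mask, k = 1L) {
  d <- dim(mask)
  for (i in seq_len(k)) {
    m <- mask
    for (ax in 1:3) {
      n <- d[ax]
      lo <- hi <- mask
      idx_lo <- c(1L, seq_len(n - 1L)); idx_hi <- c(seq_len(n - 1L) + 1L, n)
      if (ax == 1) { lo <- mask[idx_lo, , ]; hi <- mask[idx_hi, , ] }
      if (ax == 2) { lo <- mask[, idx_lo, ]; hi <- mask[, idx_hi, ] }
      if (ax == 3) { lo <- mask[, , idx_lo]; hi <- mask[, , idx_hi] }
      m <- m & lo & hi
    }
    if (!any(m)) return(mask)   # never erode to nothing
    mask <- m
  }
  mask
}

#' Fit all myocardial segments of a series
#'
#' Convenience wrapper: extracts the blood input from the core of the LV
#' cavity (the cavity mask eroded by `blood_erode_mm`, the usual defence
#' against myocardial spill-in at PET resolution) and one tissue TAC per
#' myocardial segment, then fits the one-tissue model for each.
#' Frame-duration weights are used, the standard weighting for variance that
#' scales inversely with acquisition time.
#'
#' @param series a [dynamic_series].
#' @param phantom a [build_phantom()] result supplying the LV cavity mask
#'   and segment labels (any segmentation with the same structure works).
#' @param blood_erode_mm erosion of the blood ROI in mm (default 4).
#' @param seed seed passed to each fit's multistart.
#' @return named list of `kinetic_fit`, one per segment.
#' @export
fit_segments <- function(series, phantom, blood_erode_mm = 4, seed = 1L) {
  k <- max(0L, as.integer(round(blood_erode_mm / min(series$spacing_mm))))
  blood_mask <- erode_mask(phantom$masks$lv_cavity, k)
  blood <- extract_tac(series, blood_mask)
  w <- series$schedule$duration_s
  segs <- sort(unique(phantom$segments[phantom$segments > 0]))
  fits <- lapply(segs, function(s) {
    fit_one_tissue(blood, extract_tac(series, phantom$segments == s),
                   weights = w, seed = seed)
  })
  names(fits) <- paste0("seg", segs)
  fits
}
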