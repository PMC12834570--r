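#' Per-frame rigid translation corrections
#'
#' A `motion_trace` stores, for every frame, the correction vector
#' `(tx, ty, tz)` in mm that aligns the frame to the reference: x is the
#' septal-lateral axis, y anterior-inferior, z apical-basal. The corrupting
#' displacement of a frame is the inverse of its correction.
#'
#' @param txyz numeric `n x 3` matrix (or length-3 vector for one frame) of
#'   translations in mm.
#' @param max_mm bound on any single component (default 25 mm).
#' @return Object of class `motion_trace`: an `n x 3` matrix with columns
#'   `tx`, `ty`, `tz`.
#' @export
motion_trace <- function(txyz, max_mm = 25) {
  if (is.null(dim(txyz))) txyz <- matrix(txyz, ncol = 3, byrow = TRUE)
  txyz <- as.matrix(txyz)
  stop_if(ncol(txyz) != 3L, "a motion trace needs 3 columns (tx, ty, tz)")
  stop_if(any(!is.finite(txyz)), "translations must be finite")
  stop_if(any(abs(txyz) > max_mm),
          "translation component exceeds the ", max_mm, " mm bound")
  colnames(txyz) <- c("tx", "ty", "tz")
  structure(txyz, class = c("motion_trace", "matrix"), max_mm = max_mm)
}

#' Invert a motion trace
#'
#' Componentwise negation: the correction undoing a displacement, or vice
#' versa. Involutive.
#'
#' @param trace a [motion_trace].
#' @return a [motion_trace].
#' @export
invert_trace <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  motion_trace(-unclass(trace), max_mm = attr(trace, "max_mm"))
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, mean |t| = (%.2f, %.2f, %.2f) mm\n",
              nrow(x), mean(abs(x[, 1])), mean(abs(x[, 2])), mean(abs(x[, 3]))))
  invisible(x)
}

#' Table of operator motion corrections
#'
#' Validates the long-format table of manual per-frame corrections:
#' one row per (case, phase, frame, operator), vectors in mm.
#'
#' @param df data.frame with columns `case_id`, `site_id`, `phase`
#'   (`"rest"`/`"stress"`), `frame` (0-based), `operator`, `tx_mm`, `ty_mm`,
#'   `tz_mm`.
#' @return the validated data.frame, classed `correction_table`.
#' @export
correction_table <- function(df) {
  need <- c("case_id", "site_id", "phase", "frame", "operator",
            "tx_mm", "ty_mm", "tz_mm")
  miss <- setdiff(need, names(df))
  stop_if(length(miss) > 0, "correction table missing column(s): ",
          paste(miss, collapse = ", "))
  stop_if(!all(df$phase %in% c("rest", "stress")),
          "phase must be 'rest' or 'stress'")
  key <- paste(df$case_id, df$phase, df$frame, df$operator)
  stop_if(anyDuplicated(key) > 0,
          "duplicate (case, phase, frame, operator) rows in correction table")
  stop_if(any(!is.finite(as.matrix(df[, c("tx_mm", "ty_mm", "tz_mm")]))),
          "correction vectors must be finite")
  class(df) <- c("correction_table", class(df))
  df
}

#' Fit a per-frame bootstrap motion sampler
#'
#' Builds, for every frame index and axis, the empirical pool of observed
#' operator corrections for one phase. Sampling later draws from these pools
#' with replacement, so the per-frame temporal structure of motion (e.g.
#' z-dominant early creep) is preserved while new whole-scan traces are
#' generated.
#'
#' @param table a [correction_table].
#' @param phase `"rest"` or `"stress"`.
#' @param frames frame indices (0-based) the sampler must cover; defaults to
#'   `0:max(table$frame)`. A frame with no observations is an error.
#' @param joint if `TRUE`, resample whole `(tx,ty,tz)` tuples per frame
#'   instead of independent per-axis draws.
#' @return Object of class `frame_motion_sampler`.
#' @export
fit_sampler <- function(table, phase = c("stress", "rest"), frames = NULL,
                        joint = FALSE) {
  stopifnot(inherits(table, "correction_table"))
  phase <- match.arg(phase)
  tb <- table[table$phase == phase, , drop = FALSE]
  stop_if(nrow(tb) == 0, "no rows for phase '", phase, "'")
  if (is.null(frames)) frames <- 0:max(tb$frame)
  missing_frames <- setdiff(frames, unique(tb$frame))
  stop_if(length(missing_frames) > 0,
          "no observations for frame(s): ",
          paste(missing_frames, collapse = ", "))
  pools <- lapply(frames, function(f) {
    rows <- tb[tb$frame == f, c("tx_mm", "ty_mm", "tz_mm"), drop = FALSE]
    as.matrix(rows)
  })
  names(pools) <- as.character(frames)
  structure(list(pools = pools, frames = frames, phase = phase, joint = joint),
            class = "frame_motion_sampler")
}

#' Draw bootstrap motion traces
#'
#' Each trace is sampled frame by frame with replacement from the sampler's
#' empirical pools: per axis independently by default, or as whole tuples
#' when the sampler was fitted with `joint = TRUE`. Only observed values can
#' ever be emitted.
#'
#' @param sampler a [fit_sampler()] result.
#' @param n_traces number of traces (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return list of [motion_trace], each with one row per sampler frame.
#' @export
sample_traces <- function(sampler, n_traces, seed = NULL) {
  stopifnot(inherits(sampler, "frame_motion_sampler"))
  stop_if(n_traces < 1, "n_traces must be >= 1")
  nf <- length(sampler$pools)
  with_seed(seed, {
    lapply(seq_len(n_traces), function(i) {
      tr <- matrix(0, nf, 3)
      for (f in seq_len(nf)) {
        pool <- sampler$pools[[f]]
        if (sampler$joint) {
          tr[f, ] <- pool[sample.int(nrow(pool), 1L), ]
        } else {
          for (ax in 1:3) tr[f, ax] <- pool[sample.int(nrow(pool), 1L), ax]
        }
      }
      motion_trace(tr)
    })
  })
}

#' Parametric early-frame creep trace
#'
#' Myocardial creep: a predominantly apical-basal (z) drift strongest in the
#' early post-stress frames, decaying exponentially with time. The x and y
#' components follow the same profile scaled down by `xy_scale`; seeded
#' Gaussian jitter is added per frame and axis.
#'
#' @param schedule a [frame_schedule].
#' @param z_amplitude_mm creep amplitude at t = 0 (mm, >= 0).
#' @param decay_s exponential time constant (s, > 0).
#' @param xy_scale scale of in-plane drift relative to z (< 1).
#' @param jitter_sd_mm standard deviation of per-frame jitter (mm).
#' @param seed RNG seed for the jitter.
#' @return a [motion_trace] (interpreted as the correction trace; the
#'   corrupting displacement is its inverse).
#' @export
creep_trace <- function(schedule, z_amplitude_mm, decay_s = 100,
                        xy_scale = 0.4, jitter_sd_mm = 0, seed = NULL) {
  stop_if(z_amplitude_mm < 0, "z_amplitude_mm must be >= 0")
  stop_if(decay_s <= 0, "decay_s must be positive")
  t_mid <- frame_mid_times(schedule)
  p <- z_amplitude_mm * exp(-t_mid / decay_s)
  tr <- cbind(xy_scale * p, xy_scale * p, p)
  if (jitter_sd_mm > 0) {
    tr <- tr + with_seed(seed, matrix(stats::rnorm(length(tr), 0, jitter_sd_mm),
                                      ncol = 3))
  }
  motion_trace(tr)
}

#' Translate every frame of a series
#'
#' Frame `i` is shifted by `trace[i, ]` mm (content moves in the + direction
#' of each axis); voxels pulled from outside the grid are zero-filled.
#' Millimetres are converted to voxels through the (possibly anisotropic)
#' spacing; `nearest` resampling is exact for integer-voxel shifts,
#' `trilinear` handles subvoxel shifts.
#'
#' @param series a [dynamic_series].
#' @param trace a [motion_trace] with one row per frame.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a [dynamic_series].
#' @export
apply_motion <- function(series, trace,
                         interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(series, "dynamic_series"), inherits(trace, "motion_trace"))
  interpolation <- match.arg(interpolation)
  nf <- n_frames(series)
  stop_if(nrow(trace) != nf, "trace has ", nrow(trace), " rows for ", nf, " frames")
  mode <- if (interpolation == "nearest") 0L else 1L
  d <- dim(series$voxels)[1:3]
  out <- series$voxels
  for (i in seq_len(nf)) {
    sv <- trace[i, ] / series$spacing_mm
    if (all(sv == 0)) next
    out[, , , i] <- array(shift_volume_cpp(as.numeric(series$voxels[, , , i]),
                                           d, sv, mode), dim = d)
  }
  dynamic_series(out, series$spacing_mm, series$schedule)
}

#' Apply a correction trace to a series
#'
#' Identical semantics to [apply_motion()]: the stored trace is the
#' correction added to each frame to align it with the reference, so
#' correcting a series corrupted by displacement `d` uses trace `-d`.
#'
#' @inheritParams apply_motion
#' @param correction_trace the correction [motion_trace].
#' @return a [dynamic_series].
#' @export
correct_series <- function(series, correction_trace,
                           interpolation = c("trilinear", "nearest")) {
  apply_motion(series, correction_trace, interpolation)
}

# Dice overlap of two logical masks.
dice_overlap <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
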