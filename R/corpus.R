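#' Simulate one dynamic study from the phantom
#'
#' Builds the phantom, evaluates the arterial input at the schedule
#' mid-times, derives the regional time-activity curves from the one-tissue
#' model (per-segment myocardial K1; blood cavities carry the input itself),
#' and renders the frames with PSF blur and noise. Stress multiplies the
#' myocardial K1 by `stress_k1_factor`.
#'
#' @param spec a [phantom_spec].
#' @param schedule a [frame_schedule] (default [default_schedule()]).
#' @param phase `"rest"` or `"stress"`.
#' @param stress_k1_factor hyperaemic flow multiplier (default 2.2).
#' @param seed rendering noise seed.
#' @return list with `series` (motion-free [dynamic_series]), `phantom`,
#'   `input` (blood [tac]), `truth` (data.frame of per-segment true K1),
#'   `tacs`.
#' @export
phantom_study <- function(spec = phantom_spec(), schedule = default_schedule(),
                          phase = c("rest", "stress"), stress_k1_factor = 2.2,
                          seed = NULL) {
  phase <- match.arg(phase)
  phantom <- build_phantom(spec)
  t_mid <- frame_mid_times(schedule)
  input <- make_input_function(t_mid, spec$bolus)
  myo <- spec$region_kinetics$myocardium
  bg <- spec$region_kinetics$background
  k1_seg <- unname(myo[1]) * spec$segment_k1_scale *
    if (phase == "stress") stress_k1_factor else 1
  myo_tac <- vapply(k1_seg, function(k1)
    model_tac(input, k1, myo[2], myo[3])$activity, numeric(length(t_mid)))
  tacs <- list(background = model_tac(input, bg[1], bg[2], bg[3])$activity,
               lv_cavity = input$activity,
               rv_cavity = input$activity,
               myocardium = myo_tac)
  series <- render_series(phantom, tacs, schedule, seed = seed)
  list(series = series, phantom = phantom, input = input,
       truth = data.frame(segment = paste0("seg", seq_along(k1_seg)),
                          K1 = unname(k1_seg), k2 = unname(myo[2]),
                          fv = unname(myo[3])),
       tacs = tacs)
}

#' Simulate a motion-corrupted study
#'
#' Renders a motion-free study and corrupts it with early-frame creep: the
#' ground-truth correction trace is a [creep_trace()] and the frames are
#' displaced by its inverse.
#'
#' @inheritParams phantom_study
#' @param motion list of creep parameters: `z_amplitude_mm`, `decay_s`,
#'   `xy_scale`, `jitter_sd_mm`.
#' @param seed drives rendering noise, jitter and any downstream use.
#' @return the [phantom_study()] list plus `corrupted` (a [dynamic_series])
#'   and `gt_trace` (the correction [motion_trace]).
#' @export
simulate_study <- function(spec = phantom_spec(), schedule = default_schedule(),
                           phase = "stress", stress_k1_factor = 2.2,
                           motion = list(z_amplitude_mm = 8, decay_s = 100,
                                         xy_scale = 0.4, jitter_sd_mm = 0.3),
                           seed = NULL) {
  st <- phantom_study(spec, schedule, phase, stress_k1_factor,
                      seed = child_seed(seed, "render"))
  gt <- creep_trace(schedule, motion$z_amplitude_mm,
                    motion$decay_s %||% 100, motion$xy_scale %||% 0.4,
                    motion$jitter_sd_mm %||% 0, seed = child_seed(seed, "jitter"))
  st$gt_trace <- gt
  st$corrupted <- apply_motion(st$series, invert_trace(gt))
  st
}

#' Simulate a multi-site corpus of motion-corrupted studies
#'
#' Case-to-case variation emulates a clinical population at desk scale:
#' heart position and size jitter, resting flow and hyperaemic reserve vary,
#' roughly a third of cases carry one hypoperfused segment (halved stress
#' flow), and each scan gets its own early-frame creep whose apical-basal
#' amplitude dominates the in-plane components, strongest in stress. Cases
#' are distributed round-robin over `n_sites` sites.
#'
#' @param n_cases number of cases.
#' @param n_sites number of distinct sites.
#' @param schedule a [frame_schedule].
#' @param include_rest also simulate a rest scan per case (needed for MFR).
#' @param noise_scale rendering noise level (variance per unit intensity).
#' @param grid_shape,spacing_mm phantom grid.
#' @param keep_clean retain the motion-free series in each case (needed for
#'   motion-free reference fits; drop to halve memory on large corpora).
#' @param keep_phantom retain the per-case phantom (masks and segments;
#'   needed for kinetic fitting of the case).
#' @param seed master seed; every case derives its own stream.
#' @return list of cases; each has `case_id`, `site_id`, `truth`, `phantom`,
#'   and per-phase entries (`stress`, optionally `rest`) holding `clean`,
#'   `corrupted`, `gt_trace`, `stress_k1_factor`.
#' @export
simulate_corpus <- function(n_cases, n_sites = max(2L, n_cases %/% 3L),
                            schedule = default_schedule(),
                            include_rest = FALSE, noise_scale = 0.5,
                            grid_shape = c(48L, 48L, 48L),
                            spacing_mm = c(2, 2, 2),
                            keep_clean = TRUE, keep_phantom = TRUE,
                            seed = 1L) {
  lapply(seq_len(n_cases), function(ci) {
    cseed <- child_seed(seed, paste0("case", ci))
    pars <- with_seed(cseed, {
      list(center_jit = stats::runif(3, -1.5, 1.5),
           radii_scale = stats::runif(1, 0.9, 1.04),
           k1_rest = stats::runif(1, 0.7, 1.1),
           stress_factor = stats::runif(1, 1.8, 2.6),
           diseased = stats::runif(1) < 0.35,
           diseased_seg = sample.int(6, 1),
           z_amp_stress = min(15, abs(stats::rnorm(1, 6, 3))),
           z_amp_rest = min(15, abs(stats::rnorm(1, 2.5, 1.5))),
           decay = stats::runif(1, 60, 140))
    })
    seg_scale <- c(1, 0.95, 1.05, 0.9, 1.1, 1)
    spec_for <- function(phase) {
      scale <- seg_scale
      if (pars$diseased && phase == "stress")
        scale[pars$diseased_seg] <- scale[pars$diseased_seg] * 0.5
      phantom_spec(
        grid_shape = grid_shape, spacing_mm = spacing_mm,
        lv_center_mm = (grid_shape - 1) * spacing_mm / 2 + pars$center_jit,
        lv_radii_mm = c(9, 9, 12) * pars$radii_scale,
        rv_radii_mm = c(6, 8, 10) * pars$radii_scale,
        region_kinetics = list(
          myocardium = c(K1 = pars$k1_rest, k2 = 0.12, fv = 0.30),
          background = c(K1 = 0.08, k2 = 0.05, fv = 0.05)),
        segment_k1_scale = scale,
        noise_scale = noise_scale)
    }
    one_phase <- function(phase) {
      amp <- if (phase == "stress") pars$z_amp_stress else pars$z_amp_rest
      st <- simulate_study(
        spec_for(phase), schedule, phase = phase,
        stress_k1_factor = pars$stress_factor,
        motion = list(z_amplitude_mm = amp, decay_s = pars$decay,
                      xy_scale = 0.4, jitter_sd_mm = 0.3),
        seed = child_seed(cseed, phase))
      res <- list(corrupted = st$corrupted, gt_trace = st$gt_trace,
                  truth = st$truth)
      if (keep_clean) res$clean <- st$series
      if (keep_phantom) res$phantom <- st$phantom
      res
    }
    out <- list(case_id = sprintf("case%03d", ci),
                site_id = sprintf("site%02d", 1L + (ci - 1L) %% n_sites),
                stress_k1_factor = pars$stress_factor)
    out$stress <- one_phase("stress")
    if (include_rest) out$rest <- one_phase("rest")
    if (keep_phantom) out$phantom <- out$stress$phantom
    out$truth <- out$stress$truth
    out
  })
}

#' Adapt a corpus for training
#'
#' @param corpus a [simulate_corpus()] result.
#' @param phase which phase's scans to train on.
#' @return list of cases in the shape [make_samples()] expects (`series` =
#'   the corrupted scan, `traces` = the ground-truth correction).
#' @export
corpus_training_cases <- function(corpus, phase = "stress") {
  lapply(corpus, function(cs) {
    ph <- cs[[phase]]
    stop_if(is.null(ph), "corpus has no '", phase, "' scans")
    list(series = ph$corrupted, traces = ph$gt_trace, phase = phase,
         case_id = cs$case_id, site_id = cs$site_id)
  })
}
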