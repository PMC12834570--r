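make_table <- function(z_pool = c(0, 2, 4), n_frames = 4) {
  rows <- expand.grid(frame = 0:(n_frames - 1), case = seq_along(z_pool))
  correction_table(data.frame(
    case_id = paste0("c", rows$case), site_id = "s1", phase = "stress",
    frame = rows$frame, operator = 1L,
    tx_mm = 0.5 * z_pool[rows$case], ty_mm = 0.25 * z_pool[rows$case],
    tz_mm = z_pool[rows$case]))
}

test_that("a single-case pool reproduces that case exactly", {
  tb <- make_table(z_pool = 3, n_frames = 5)
  smp <- fit_sampler(tb, "stress")
  tr <- sample_traces(smp, 4, seed = 1)
  for (t in tr) expect_equal(unclass(t), cbind(tx = rep(1.5, 5),
                                               ty = rep(0.75, 5),
                                               tz = rep(3, 5)),
                             ignore_attr = TRUE)
})

test_that("bootstrap draws stay on the observed support with the right mean", {
  smp <- fit_sampler(make_table(), "stress")
  draws <- sample_traces(smp, 2500, seed = 7)   # 10^4 frame-4 z-draws
  z <- vapply(draws, function(t) t[4, 3], 0)
  z_all <- unlist(lapply(draws, function(t) t[, 3]))
  expect_true(all(z_all %in% c(0, 2, 4)))
  expect_lt(abs(mean(z) - 2), 3 * sqrt(8 / 3) / sqrt(length(z)))
  # empirical frequencies match the multinomial oracle within 3 sigma
  for (v in c(0, 2, 4)) {
    p <- mean(z == v)
    expect_lt(abs(p - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / length(z)))
  }
})

test_that("sampler covers only the requested phase and flags missing frames", {
  tb <- make_table()
  tb2 <- tb
  tb2$phase <- "rest"
  tb2$tz_mm <- tb2$tz_mm + 100
  both <- correction_table(rbind(as.data.frame(tb), as.data.frame(tb2)))
  smp <- fit_sampler(both, "stress")
  expect_true(all(unlist(lapply(smp$pools, function(p) p[, "tz_mm"])) <= 4))
  expect_error(fit_sampler(tb, "stress", frames = 0:9), "frame\\(s\\): 4")
})

test_that("sampling is seed-reproducible and preserves pool marginals", {
  smp <- fit_sampler(make_table(), "stress")
  a <- sample_traces(smp, 10, seed = 3)
  b <- sample_traces(smp, 10, seed = 3)
  expect_identical(a, b)
  big <- sample_traces(smp, 3000, seed = 4)
  z1 <- vapply(big, function(t) t[1, 3], 0)
  expect_lt(abs(mean(z1) - 2), 0.1)
  expect_lt(abs(stats::sd(z1) - sqrt(8 / 3)), 0.1)
})

test_that("traces sampled from z-dominant pools stay z-dominant", {
  # pools built from creep-like corrections: apical-basal motion dominates
  # the in-plane axes, as reported for stress acquisitions
  sch <- frame_schedule(seq(0, 90, by = 10), rep(10, 10))
  set.seed(5)
  rows <- do.call(rbind, lapply(1:20, function(ci) {
    tr <- creep_trace(sch, abs(rnorm(1, 6, 3)), 100, xy_scale = 0.35,
                      jitter_sd_mm = 0.4, seed = ci)
    data.frame(case_id = paste0("c", ci), site_id = "s1", phase = "stress",
               frame = 0:9, operator = 1L,
               tx_mm = tr[, 1], ty_mm = tr[, 2], tz_mm = tr[, 3])
  }))
  smp <- fit_sampler(correction_table(rows), "stress")
  drawn <- sample_traces(smp, 1000, seed = 6)
  m <- colMeans(do.call(rbind, lapply(drawn, function(t) colMeans(abs(t)))))
  expect_gt(m["tz"], m["tx"])
  expect_gt(m["tz"], m["ty"])
})

test_that("creep traces follow the closed-form early-frame decay", {
  sch <- frame_schedule(c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                        rep(10, 10))
  expect_true(all(creep_trace(sch, 0, 60) == 0))
  tr <- creep_trace(sch, 8, 60, xy_scale = 0.5)
  tm <- frame_mid_times(sch)
  expect_equal(tr[, 3], 8 * exp(-tm / 60))
  expect_equal(tr[, 1], 0.5 * tr[, 3])
  expect_true(all(diff(tr[, 3]) < 0))
  expect_gt(mean(abs(tr[1:5, 3])), mean(abs(tr[6:10, 3])))
})

test_that("integer-voxel nearest shifts match the index-roll oracle", {
  st <- tiny_study()
  ser <- st$series
  tr <- motion_trace(matrix(rep(c(8, -4, 12), each = 10), 10, 3))  # 2,-1,3 voxels
  out <- apply_motion(ser, tr, "nearest")
  for (i in c(1, 5, 10)) {
    expect_equal(out$voxels[, , , i],
                 roll_shift(ser$voxels[, , , i], c(2, -1, 3)))
  }
  # zero trace is the identity
  z <- apply_motion(ser, motion_trace(matrix(0, 10, 3)))
  expect_identical(z$voxels, ser$voxels)
  expect_error(apply_motion(ser, motion_trace(matrix(0, 4, 3))), "rows")
})

test_that("half-voxel trilinear round trips equal the exact smoothing kernel", {
  # shifting by +h then -h voxels with trilinear resampling is, on interior
  # voxels, exactly a separable [h(1-h)/... ] 3-tap smoothing; for h = 1/2
  # the taps are [0.25, 0.5, 0.25]. Oracle: direct kernel convolution.
  st <- tiny_study()
  ser <- st$series
  tr <- motion_trace(matrix(rep(c(2, 0, 2), each = 10), 10, 3))  # 0.5 voxels
  back <- apply_motion(apply_motion(ser, tr), invert_trace(tr))
  smooth1d <- function(v, ax) {
    d <- dim(v)
    idx <- function(s) {
      i <- pmin(pmax(seq_len(d[ax]) + s, 1L), d[ax])
      switch(ax, v[i, , ], v[, i, ], v[, , i])
    }
    0.25 * idx(-1L) + 0.5 * idx(0L) + 0.25 * idx(1L)
  }
  for (f in c(1, 6)) {
    oracle <- smooth1d(smooth1d(ser$voxels[, , , f], 1), 3)
    expect_equal(back$voxels[3:22, 3:22, 3:22, f],
                 oracle[3:22, 3:22, 3:22], tolerance = 1e-12)
  }
})

test_that("invert_trace is componentwise negation and involutive", {
  tr <- motion_trace(rbind(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(unclass(invert_trace(tr))[1, ], c(tx = -1, ty = -2, tz = -3))
  expect_equal(unclass(invert_trace(invert_trace(tr))), unclass(tr))
})

test_that("correcting with the inverted trace restores the series", {
  st <- tiny_study()
  ser <- st$series
  tr <- motion_trace(matrix(rep(c(8, -4, 4), each = 10), 10, 3))
  round_trip <- correct_series(apply_motion(ser, tr, "nearest"),
                               invert_trace(tr), "nearest")
  # voxels never zero-filled: stay 3+ voxels from every face
  expect_equal(round_trip$voxels[5:20, 5:20, 5:20, ],
               ser$voxels[5:20, 5:20, 5:20, ])
})

test_that("correcting a creep-corrupted series restores myocardial overlap", {
  st <- tiny_study()
  gt <- creep_trace(tiny_schedule(), 10, decay_s = 100)
  corrupted <- apply_motion(st$series, invert_trace(gt))
  corrected <- correct_series(corrupted, gt)
  myo <- st$phantom$masks$myocardium
  # track the mask through the same displacements
  d <- dim(myo)
  for (i in c(1, 2, 3)) {
    sv <- unclass(gt)[i, ] / st$series$spacing_mm
    moved <- array(petmoco:::shift_volume_cpp(as.numeric(myo), d, -sv, 0L), dim = d) > 0.5
    fixed <- array(petmoco:::shift_volume_cpp(as.numeric(moved), d, sv, 0L), dim = d) > 0.5
    expect_gte(petmoco:::dice_overlap(fixed, myo),
               petmoco:::dice_overlap(moved, myo))
    expect_gt(petmoco:::dice_overlap(fixed, myo), 0.9)
  }
})

test_that("motion traces validate their bound and finiteness", {
  expect_error(motion_trace(rbind(c(30, 0, 0))), "25 mm")
  expect_error(motion_trace(rbind(c(NA, 0, 0))), "finite")
  expect_s3_class(motion_trace(rbind(c(30, 0, 0)), max_mm = 50), "motion_trace")
})
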