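test_that("frame schedules enforce timing invariants", {
  expect_s3_class(frame_schedule(c(0, 10), c(10, 20)), "frame_schedule")
  expect_error(frame_schedule(c(5, 10), c(5, 5)), "start at 0")
  expect_error(frame_schedule(c(0, 0), c(5, 5)), "ascending")
  expect_error(frame_schedule(c(0, 10), c(0, 5)), "positive")
  expect_error(frame_schedule(c(0, 5), c(10, 5)), "overlap")
  expect_equal(frame_mid_times(frame_schedule(c(0, 10, 20), c(10, 10, 60))),
               c(5, 15, 50))
})

test_that("region masks partition the grid", {
  ph <- build_phantom(tiny_spec())
  m <- ph$masks
  total <- m$background + m$lv_cavity + m$myocardium + m$rv_cavity
  expect_true(all(total == 1))
  expect_true(all(sort(unique(as.integer(ph$labels))) == 0:3))
  expect_true(all(ph$segments[ph$masks$myocardium] %in% 1:6))
  expect_true(all(ph$segments[!ph$masks$myocardium] == 0))
})

test_that("myocardium voxel count matches the brute-force shell inequality", {
  spec <- phantom_spec()  # default 48^3 at 2 mm
  ph <- build_phantom(spec)
  d <- spec$grid_shape; sp <- spec$spacing_mm
  cen <- spec$lv_center_mm
  r_in <- spec$lv_radii_mm
  r_out <- spec$lv_radii_mm + spec$wall_mm
  count <- 0L
  for (k in 0:(d[3] - 1)) {
    z2i <- ((k * sp[3] - cen[3]) / r_in[3])^2
    z2o <- ((k * sp[3] - cen[3]) / r_out[3])^2
    for (j in 0:(d[2] - 1)) {
      y2i <- ((j * sp[2] - cen[2]) / r_in[2])^2
      y2o <- ((j * sp[2] - cen[2]) / r_out[2])^2
      x <- (0:(d[1] - 1)) * sp[1]
      qi <- ((x - cen[1]) / r_in[1])^2 + y2i + z2i
      qo <- ((x - cen[1]) / r_out[1])^2 + y2o + z2o
      count <- count + sum(qo <= 1 & qi > 1)
    }
  }
  expect_identical(sum(ph$masks$myocardium), count)
})

test_that("zero LV radius gives an empty cavity but a filled shell", {
  spec <- tiny_spec(lv_radii_mm = c(0, 0, 0))
  ph <- build_phantom(spec)
  expect_identical(sum(ph$masks$lv_cavity), 0L)
  # shell degenerates to the filled wall ellipsoid
  expect_gt(sum(ph$masks$myocardium), 0)
})

test_that("geometry that does not fit is rejected naming the radius", {
  expect_error(tiny_spec(lv_radii_mm = c(9, 9, 40)),
               "radius 47.*does not fit")
})

test_that("input function is causal with a single gamma-variate peak", {
  t_dense <- seq(0, 300, by = 0.05)
  bolus <- list(amplitude = 100, delay_s = 10, peak_s = 25, shape = 3,
                recirc_frac = 0.12)
  ca <- make_input_function(t_dense, bolus)
  expect_true(all(ca$activity[t_dense < 10] == 0))
  expect_true(all(ca$activity >= 0))
  # independent closed-form oracle for the peak location
  td <- pmax(0, t_dense - bolus$delay_s)
  oracle <- ifelse(t_dense > bolus$delay_s,
                   bolus$amplitude *
                     ((td / bolus$peak_s)^bolus$shape *
                        exp(bolus$shape * (1 - td / bolus$peak_s)) +
                        bolus$recirc_frac * (1 - exp(-td / 60)) * exp(-td / 600)),
                   0)
  expect_equal(t_dense[which.max(ca$activity)], t_dense[which.max(oracle)])
  expect_equal(ca$activity, oracle)
  # degenerate cases
  expect_true(all(make_input_function(t_dense,
    utils::modifyList(bolus, list(amplitude = 0)))$activity == 0))
  expect_error(make_input_function(t_dense,
    utils::modifyList(bolus, list(shape = -1))), "shape")
})

test_that("noise-free, PSF-free rendering paints regions exactly", {
  spec <- tiny_spec(psf_fwhm_mm = 0, noise_scale = 0)
  ph <- build_phantom(spec)
  sch <- frame_schedule(c(0, 120), c(60, 60))
  tacs <- list(background = c(1, 2), lv_cavity = c(10, 20),
               rv_cavity = c(5, 6), myocardium = c(3, 4))
  ser <- render_series(ph, tacs, sch)
  f1 <- ser$voxels[, , , 1]
  expect_true(all(f1[ph$masks$lv_cavity] == 10))
  expect_true(all(f1[ph$masks$myocardium] == 3))
  expect_true(all(f1[ph$masks$background] == 1))
  expect_true(all(ser$voxels[, , , 2][ph$masks$rv_cavity] == 6))
})

test_that("Gaussian PSF conserves interior activity", {
  spec <- tiny_spec(psf_fwhm_mm = 8, noise_scale = 0)
  ph <- build_phantom(spec)
  sch <- frame_schedule(c(0, 120), c(60, 60))
  # background zero: all activity is interior, so blur must conserve the sum
  tacs <- list(background = c(0, 0), lv_cavity = c(10, 20),
               rv_cavity = c(5, 6), myocardium = c(3, 4))
  ser <- render_series(ph, tacs, sch)
  expected <- 10 * sum(ph$masks$lv_cavity) + 5 * sum(ph$masks$rv_cavity) +
    3 * sum(ph$masks$myocardium)
  expect_equal(sum(ser$voxels[, , , 1]), expected, tolerance = 1e-8)
})

test_that("rendering is reproducible under a fixed seed", {
  spec <- tiny_spec(noise_scale = 1)
  ph <- build_phantom(spec)
  sch <- frame_schedule(c(0, 120), c(60, 60))
  tacs <- list(background = c(1, 1), lv_cavity = c(10, 10),
               rv_cavity = c(5, 5), myocardium = c(3, 3))
  s1 <- render_series(ph, tacs, sch, seed = 42)
  s2 <- render_series(ph, tacs, sch, seed = 42)
  s3 <- render_series(ph, tacs, sch, seed = 43)
  expect_identical(s1$voxels, s2$voxels)
  expect_false(identical(s1$voxels, s3$voxels))
  # TAC length mismatch is rejected
  expect_error(render_series(ph, utils::modifyList(tacs, list(lv_cavity = 1:3)),
                             sch), "3 values")
})

test_that("noise-free myocardial TAC survives render + extract round trip", {
  spec <- tiny_spec(psf_fwhm_mm = 0, noise_scale = 0)
  ph <- build_phantom(spec)
  sch <- tiny_schedule()
  input <- make_input_function(frame_mid_times(sch), spec$bolus)
  myo <- model_tac(input, 0.9, 0.12, 0.3)
  tacs <- list(background = rep(0, 10), lv_cavity = input$activity,
               rv_cavity = input$activity, myocardium = myo$activity)
  ser <- render_series(ph, tacs, sch)
  got <- extract_tac(ser, ph$masks$myocardium)
  expect_equal(got$activity, myo$activity, tolerance = 1e-12)
})
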