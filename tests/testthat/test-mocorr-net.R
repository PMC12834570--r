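test_that("the reference sums exactly the frames after the cutoff", {
  sch <- frame_schedule(c(0, 60, 120, 180), rep(60, 4))
  vox <- array(1, dim = c(6, 6, 6, 4))
  ser <- dynamic_series(vox, c(2, 2, 2), sch)
  ref <- build_reference(ser, 120)
  expect_true(all(ref$volume == 2))   # two frames start at >= 120 s
  expect_true(all(build_reference(ser, 0)$volume == 4))
  expect_error(build_reference(ser, 500), "no frames")
  # naive-loop oracle on random intensities
  set.seed(1)
  ser2 <- dynamic_series(array(rnorm(6^3 * 4), c(6, 6, 6, 4)), c(2, 2, 2), sch)
  acc <- array(0, c(6, 6, 6))
  for (i in which(sch$start_s >= 120)) acc <- acc + ser2$voxels[, , , i]
  expect_equal(build_reference(ser2, 120)$volume, acc)
})

test_that("preprocessing centres, rescales and is intensity-scale invariant", {
  st <- tiny_study()
  ref <- build_reference(st$series)
  fr <- st$series$voxels[, , , 3]
  cfg <- moco_config(grid = 16L)
  pp <- preprocess_pair(fr, ref, st$series$spacing_mm, cfg)
  expect_equal(dim(pp$mov), rep(16L, 3))
  expect_true(all(pp$mov >= 0 & pp$mov <= 1))
  # scaling the inputs by 10 changes nothing
  pp10 <- preprocess_pair(10 * fr, list(volume = 10 * ref$volume) |>
                            (\(x) { class(x) <- "reference_volume"; x })(),
                          st$series$spacing_mm, cfg)
  expect_equal(pp10$mov, pp$mov, tolerance = 1e-12)
  # centroid of the preprocessed reference sits at the grid centre
  cen_vox <- petmoco:::intensity_centroid(pp$ref, pp$out_spacing_mm) /
    pp$out_spacing_mm
  expect_true(all(abs(cen_vox - (16 - 1) / 2) < 1))
  # constant-positive volume maps to all ones
  const <- array(5, dim = dim(fr))
  ppc <- preprocess_pair(const, const, st$series$spacing_mm, cfg)
  expect_true(all(ppc$mov == 1))
  expect_error(preprocess_pair(fr, array(0, dim = dim(fr)),
                               st$series$spacing_mm, cfg), "empty")
})

test_that("the regressor is well-posed and has no cross-sample coupling", {
  cfg <- moco_config(grid = 16L, base_channels = 4L, seed = 2L)
  net <- build_regressor(cfg)
  B <- 3L
  set.seed(3)
  mov <- runif(16^3 * B); ref <- runif(16^3 * B); fidx <- c(0, 0.5, 1)
  out <- petmoco:::net_forward(net, mov, ref, fidx)$pred
  expect_equal(dim(out), c(3L, 3L))
  expect_true(all(is.finite(out)))
  zero <- petmoco:::net_forward(net, numeric(16^3), numeric(16^3), 0)$pred
  expect_true(all(is.finite(zero)))
  # permuting the batch permutes the outputs identically
  perm <- c(3L, 1L, 2L)
  ix <- function(v, p) as.numeric(matrix(v, ncol = B)[, p])
  out_p <- petmoco:::net_forward(net, ix(mov, perm), ix(ref, perm),
                                 fidx[perm])$pred
  expect_equal(out_p, out[, perm], tolerance = 1e-12)
  expect_error(moco_config(grid = 20L), "downsampling depth")
})

test_that("a zeroed regression head forces an all-zero trace", {
  st <- tiny_study()
  cfg <- moco_config(grid = 16L, base_channels = 4L, seed = 2L)
  net <- build_regressor(cfg)
  net$params[["fc.W"]][] <- 0
  net$params[["fc.b"]][] <- 0
  tr <- predict_trace(net, st$series)
  expect_true(all(tr == 0))
  # prediction invariant to global intensity scaling
  net2 <- build_regressor(cfg)
  scaled <- dynamic_series(st$series$voxels * 37, st$series$spacing_mm,
                           st$series$schedule)
  expect_equal(unclass(predict_trace(net2, scaled)),
               unclass(predict_trace(net2, st$series)), tolerance = 1e-9)
})

test_that("make_samples counts frames and honours the sign convention", {
  st <- tiny_study()
  cfg <- moco_config(grid = 16L)
  zero_tr <- motion_trace(matrix(0, 10, 3))
  cases <- list(list(series = st$series, traces = zero_tr,
                     case_id = "a", site_id = "s1"))
  ts0 <- make_samples(cases, config = cfg)
  expect_equal(ncol(ts0$mov), 10L)
  expect_true(all(ts0$target == 0))
  # one-trace pool: the sampled augmentation trace is that trace, and with a
  # zero operator correction the target must equal it (corruption d => -d)
  aug_tr <- creep_trace(tiny_schedule(), 6, 100)
  tb <- petmoco:::traces_to_table(list(list(series = st$series, traces = aug_tr,
                                            case_id = "p", site_id = "s")))
  sampler <- fit_sampler(tb, "stress")
  ts1 <- make_samples(cases, sampler, n_aug_per_case = 1L, config = cfg,
                      seed = 9)
  expect_equal(ncol(ts1$mov), 20L)
  aug_targets <- t(ts1$target[, ts1$augmented])
  expect_equal(unname(aug_targets), unname(unclass(aug_tr)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # the augmented moving frame is the clean frame displaced by -target
  i <- which(ts1$augmented)[1]
  d <- unclass(aug_tr)[1, ] / st$series$spacing_mm
  shifted <- array(petmoco:::shift_volume_cpp(
    as.numeric(st$series$voxels[, , , 1]), dim(st$series$voxels)[1:3], -d, 1L),
    dim = dim(st$series$voxels)[1:3])
  ref_aug <- build_reference(apply_motion(st$series, invert_trace(aug_tr)))
  pp <- preprocess_pair(shifted, ref_aug, st$series$spacing_mm, cfg)
  expect_equal(ts1$mov[, i], as.numeric(pp$mov), tolerance = 1e-12)
})

test_that("the operator randomizer is seeded and uses both operators", {
  st <- tiny_study()
  cfg <- moco_config(grid = 16L)
  tr1 <- motion_trace(matrix(1, 10, 3))
  tr2 <- motion_trace(matrix(-1, 10, 3))
  cases <- lapply(1:10, function(i)
    list(series = st$series, traces = list(tr1, tr2),
         case_id = paste0("c", i), site_id = "s"))
  a <- make_samples(cases, config = cfg, seed = 11)
  b <- make_samples(cases, config = cfg, seed = 11)
  expect_identical(a$operator, b$operator)
  ops <- unique(a$operator)
  expect_setequal(ops, c(1L, 2L))
  expect_true(all(a$target %in% c(-1, 1)))
})

test_that("site splitting is balanced and site-disjoint", {
  ct <- data.frame(case_id = 1:5, site_id = letters[1:5])
  sp <- split_by_site(ct, k = 5, seed = 1)
  expect_equal(sort(table(sp$cases$fold)), sort(table(0:4)))
  # the trial layout: 231 cases over 32 sites -> folds of 46 or 47
  sizes <- c(2, 2, 2, 2, 8, 10, 6, 7, 9, 7, 14, 2, 6, 4, 13, 14, 14, 7, 7, 2,
             11, 11, 7, 4, 2, 4, 12, 13, 14, 10, 2, 3)
  ct2 <- data.frame(case_id = seq_len(sum(sizes)),
                    site_id = rep(paste0("s", seq_along(sizes)), sizes))
  sp2 <- split_by_site(ct2, k = 5, seed = 1)
  fold_sizes <- as.integer(table(sp2$cases$fold))
  expect_true(all(fold_sizes %in% c(46L, 47L)))
  ag <- unique(sp2$cases[, c("site_id", "fold")])
  expect_equal(nrow(ag), 32L)   # each site in exactly one fold
  expect_error(split_by_site(ct, k = 6), "fewer sites")
})

test_that("training is deterministic and reduces loss on a small corpus", {
  st <- tiny_study()
  cfg <- moco_config(grid = 16L, base_channels = 4L, epochs = 3L, seed = 5L)
  tr <- creep_trace(tiny_schedule(), 5, 100, seed = 2)
  cases <- list(list(series = apply_motion(st$series, invert_trace(tr)),
                     traces = tr, case_id = "a", site_id = "s1"))
  ts <- make_samples(cases, config = cfg, seed = 1)
  m1 <- train_regressor(ts, cfg)
  m2 <- train_regressor(ts, cfg)
  expect_identical(m1$history, m2$history)
  expect_lte(m1$history[length(m1$history)], m1$history[1])
})

test_that("the regressor memorises a single repeated sample", {
  cfg <- moco_config(grid = 8L, base_channels = 2L, epochs = 150L,
                     lr = 2e-2, batch_size = 1L, seed = 6L)
  set.seed(7)
  vol <- runif(8^3)
  ts <- structure(list(
    mov = matrix(rep(vol, 4), ncol = 4), ref = matrix(runif(8^3), ncol = 1),
    ref_of = rep(1L, 4), target = matrix(rep(c(1, -2, 3), 4), 3),
    frame_norm = rep(0.5, 4), frame = rep(1L, 4),
    case_id = rep("a", 4), site_id = rep("s", 4),
    operator = rep(1L, 4), augmented = rep(FALSE, 4), grid = 8L),
    class = "moco_training_set")
  m <- train_regressor(ts, cfg)
  expect_lt(m$history[length(m$history)], 1e-2)
})

test_that("cross-validation reports one error row per fold and axis", {
  st1 <- tiny_study(seed = 1)
  st2 <- tiny_study(seed = 2)
  cfg <- moco_config(grid = 16L, base_channels = 2L, epochs = 1L, seed = 3L)
  zero <- motion_trace(matrix(0, 10, 3))
  cases <- list(
    list(series = st1$series, traces = zero, case_id = "a", site_id = "s1"),
    list(series = st2$series, traces = zero, case_id = "b", site_id = "s2"))
  tab <- crossval_evaluate(cases, k = 2L, config = cfg, seed = 4L)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$axis), c("x", "y", "z"))
  expect_true(all(tab$avg_error_mm >= 0))
  expect_true(all(tab$max_error_mm >= tab$avg_error_mm - 1e-12))
  expect_equal(nrow(attr(tab, "summary")), 3L)
})
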