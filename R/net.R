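#' Configuration of the translation-regression network
#'
#' Desk-scale defaults: a dual-input residual 3D convolutional regressor with
#' weight-shared stems, two residual stages, and a fully connected head
#' predicting the per-frame correction `(tx, ty, tz)` in mm. Sizes are chosen
#' so that cross-validation over the synthetic corpus runs on a single CPU.
#'
#' @param grid cubic input size after preprocessing; must be divisible by 8
#'   (two stem strides and one stage downsampling).
#' @param base_channels channels of the first stem convolution.
#' @param blocks residual blocks per stage.
#' @param share_stem if `TRUE` (default) the two input volumes pass through
#'   one weight-shared (Siamese) stem; otherwise separate stems are learned.
#' @param include_frame_index append the normalised frame number as an extra
#'   scalar input to the regression head (default `TRUE`); it carries the
#'   temporal motion prior for frames with almost no counts.
#' @param loss `"mse"` (default) or `"huber"`.
#' @param huber_delta transition point (mm) of the Huber loss.
#' @param lr,batch_size,epochs Adam learning rate, minibatch size, epochs.
#' @param cutoff_s late-frame cutoff used to build the alignment reference.
#' @param max_motion_mm bound on |component| of any target or prediction.
#' @param seed seed for weight initialisation and minibatch shuffling.
#' @return Object of class `moco_config`.
#' @export
moco_config <- function(grid = 32L, base_channels = 8L, blocks = 1L,
                        share_stem = TRUE, include_frame_index = TRUE,
                        loss = c("mse", "huber"), huber_delta = 3,
                        lr = 1e-3, batch_size = 8L, epochs = 8L,
                        cutoff_s = 120, max_motion_mm = 25, seed = 1L) {
  loss <- match.arg(loss)
  stop_if(grid < 8 || grid %% 8 != 0,
          "grid (", grid, ") incompatible with downsampling depth; must be a multiple of 8")
  stop_if(base_channels < 1 || blocks < 1 || batch_size < 1 || epochs < 1,
          "counts must be >= 1")
  stop_if(lr <= 0, "learning rate must be positive")
  structure(list(grid = as.integer(grid), base_channels = as.integer(base_channels),
                 blocks = as.integer(blocks), share_stem = share_stem,
                 include_frame_index = include_frame_index, loss = loss,
                 huber_delta = huber_delta, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 cutoff_s = cutoff_s, max_motion_mm = max_motion_mm,
                 seed = as.integer(seed)),
            class = "moco_config")
}

conv_init <- function(cout, cin, k, fc = FALSE) {
  fan_in <- cin * k^3
  matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
}

#' Build an untrained translation regressor
#'
#' Two (optionally weight-shared) convolutional stems downsample the moving
#' and reference volumes by 4x each; their feature maps are concatenated,
#' mixed by a 1x1 convolution, refined by residual blocks, downsampled once
#' more, refined again, and flattened into a fully connected head that emits
#' the three translation components in mm. Flattening (rather than global
#' average pooling) retains the coarse spatial layout that encodes the
#' displacement.
#'
#' @param config a [moco_config()].
#' @return Object of class `moco_net` (untrained: empty loss history).
#' @export
build_regressor <- function(config = moco_config()) {
  stopifnot(inherits(config, "moco_config"))
  g <- config$grid; c1 <- config$base_channels; c2 <- 2L * c1
  params <- list()
  with_seed(config$seed, {
    stems <- if (config$share_stem) "stem" else c("stem_mov", "stem_ref")
    for (s in stems) {
      params[[paste0(s, ".c1.W")]] <- conv_init(c1, 1, 3)
      params[[paste0(s, ".c1.b")]] <- numeric(c1)
      params[[paste0(s, ".c2.W")]] <- conv_init(c2, c1, 3)
      params[[paste0(s, ".c2.b")]] <- numeric(c2)
    }
    params[["reduce.W"]] <- conv_init(c2, 2L * c2, 1)
    params[["reduce.b"]] <- numeric(c2)
    for (stage in 1:2) for (bl in seq_len(config$blocks)) {
      for (half in c("a", "b")) {
        nm <- sprintf("s%db%d.%s", stage, bl, half)
        params[[paste0(nm, ".W")]] <- conv_init(c2, c2, 3)
        params[[paste0(nm, ".b")]] <- numeric(c2)
      }
    }
    params[["down.W"]] <- conv_init(c2, c2, 3)
    params[["down.b"]] <- numeric(c2)
    nfeat <- c2 * (g %/% 8L)^3 + as.integer(config$include_frame_index)
    params[["fc.W"]] <- matrix(stats::rnorm(3 * nfeat, sd = sqrt(1 / nfeat)), 3, nfeat)
    params[["fc.b"]] <- numeric(3)
  })
  structure(list(params = params, config = config, history = numeric(0)),
            class = "moco_net")
}

#' @export
print.moco_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<moco_net> grid %d^3, %d base channels, %d block(s)/stage, %d parameters\n",
              x$config$grid, x$config$base_channels, x$config$blocks, np))
  if (length(x$history)) {
    cat(sprintf("  trained %d epochs, final loss %.4g mm^2\n",
                length(x$history), x$history[length(x$history)]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
plot.moco_net <- function(x, ...) {
  stop_if(!length(x$history), "model has no training history")
  graphics::plot(seq_along(x$history), x$history, type = "b",
                 xlab = "epoch", ylab = "training loss (mm^2)", ...)
  invisible(x)
}

# --- forward / backward -----------------------------------------------------
# Feature tensors are flat numeric vectors with dims (d, d, d, C, B); relu
# masks and conv inputs are cached for the backward pass.

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}

net_forward <- function(net, mov, ref, fidx = NULL, want_cache = FALSE) {
  cfg <- net$config; p <- net$params
  g <- cfg$grid; c1 <- cfg$base_channels; c2 <- 2L * c1
  B <- length(mov) %/% (g^3)
  ca <- list()
  stem_branch <- function(x, prefix) {
    d1 <- c(g, g, g, 1L, B)
    o1 <- conv3d_fwd_cpp(x, d1, p[[paste0(prefix, ".c1.W")]],
                         p[[paste0(prefix, ".c1.b")]], 3L, 2L, 1L)
    r1 <- relu_fwd(o1$y)
    o2 <- conv3d_fwd_cpp(r1$y, o1$dim, p[[paste0(prefix, ".c2.W")]],
                         p[[paste0(prefix, ".c2.b")]], 3L, 2L, 1L)
    r2 <- relu_fwd(o2$y)
    list(x = x, d1 = d1, m1 = r1$mask, r1 = r1$y, d2 = o1$dim,
         m2 = r2$mask, y = r2$y, dy = o2$dim)
  }
  s_mov <- if (cfg$share_stem) "stem" else "stem_mov"
  s_ref <- if (cfg$share_stem) "stem" else "stem_ref"
  bm <- stem_branch(mov, s_mov)
  br <- stem_branch(ref, s_ref)
  g4 <- g %/% 4L; v4 <- g4^3
  # channel concatenation: (v4, c2, B) + (v4, c2, B) -> (v4, 2*c2, B)
  am <- array(bm$y, c(v4, c2, B)); ar <- array(br$y, c(v4, c2, B))
  cc <- array(0, c(v4, 2L * c2, B))
  cc[, seq_len(c2), ] <- am
  cc[, c2 + seq_len(c2), ] <- ar
  xcat <- as.numeric(cc)
  dcat <- c(g4, g4, g4, 2L * c2, B)
  red <- conv3d_fwd_cpp(xcat, dcat, p[["reduce.W"]], p[["reduce.b"]], 1L, 1L, 0L)
  rr <- relu_fwd(red$y)
  if (want_cache) ca <- list(bm = bm, br = br, xcat = xcat, dcat = dcat,
                             red_mask = rr$mask)
  run_stage <- function(x, dims, stage) {
    blocks <- list()
    for (bl in seq_len(cfg$blocks)) {
      nm <- sprintf("s%db%d", stage, bl)
      oa <- conv3d_fwd_cpp(x, dims, p[[paste0(nm, ".a.W")]],
                           p[[paste0(nm, ".a.b")]], 3L, 1L, 1L)
      ra <- relu_fwd(oa$y)
      ob <- conv3d_fwd_cpp(ra$y, oa$dim, p[[paste0(nm, ".b.W")]],
                           p[[paste0(nm, ".b.b")]], 3L, 1L, 1L)
      pre <- ob$y + x
      ro <- relu_fwd(pre)
      blocks[[bl]] <- list(x = x, ma = ra$mask, ha = ra$y, mo = ro$mask)
      x <- ro$y
    }
    list(y = x, blocks = blocks, dims = dims)
  }
  st1 <- run_stage(rr$y, red$dim, 1L)
  dn <- conv3d_fwd_cpp(st1$y, red$dim, p[["down.W"]], p[["down.b"]], 3L, 2L, 1L)
  rd <- relu_fwd(dn$y)
  st2 <- run_stage(rd$y, dn$dim, 2L)
  nf0 <- c2 * (g %/% 8L)^3
  X <- matrix(st2$y, nf0, B)
  if (cfg$include_frame_index) {
    stop_if(is.null(fidx) || length(fidx) != B,
            "frame indices required: config includes the frame-number input")
    X <- rbind(X, as.numeric(fidx))
  }
  pred <- p[["fc.W"]] %*% X + p[["fc.b"]]
  if (want_cache) {
    ca <- c(ca, list(st1 = st1, down_in_dims = red$dim, dn_dim = dn$dim,
                     down_mask = rd$mask, rd = rd$y, st2 = st2, X = X, B = B))
  }
  list(pred = pred, cache = if (want_cache) ca else NULL)
}

net_backward <- function(net, cache, dpred) {
  cfg <- net$config; p <- net$params
  g <- cfg$grid; c1 <- cfg$base_channels; c2 <- 2L * c1
  B <- cache$B
  gr <- list()
  addg <- function(nm, val) {
    gr[[nm]] <<- if (is.null(gr[[nm]])) val else gr[[nm]] + val
  }
  addg("fc.W", dpred %*% t(cache$X))
  addg("fc.b", rowSums(dpred))
  dX <- t(p[["fc.W"]]) %*% dpred
  if (cfg$include_frame_index) dX <- dX[-nrow(dX), , drop = FALSE]
  dy <- as.numeric(dX)
  back_stage <- function(dy, st, stage) {
    for (bl in rev(seq_len(cfg$blocks))) {
      nm <- sprintf("s%db%d", stage, bl)
      b <- st$blocks[[bl]]
      dy <- dy * b$mo
      bb <- conv3d_bwd_cpp(b$ha, st$dims, dy, p[[paste0(nm, ".b.W")]], 3L, 1L, 1L)
      addg(paste0(nm, ".b.W"), bb$dw); addg(paste0(nm, ".b.b"), bb$db)
      dh <- bb$dx * b$ma
      ba <- conv3d_bwd_cpp(b$x, st$dims, dh, p[[paste0(nm, ".a.W")]], 3L, 1L, 1L)
      addg(paste0(nm, ".a.W"), ba$dw); addg(paste0(nm, ".a.b"), ba$db)
      dy <- ba$dx + dy   # skip connection
    }
    dy
  }
  dy <- back_stage(dy, cache$st2, 2L)
  dy <- dy * cache$down_mask
  bd <- conv3d_bwd_cpp(cache$st1$y, cache$down_in_dims, dy, p[["down.W"]], 3L, 2L, 1L)
  addg("down.W", bd$dw); addg("down.b", bd$db)
  dy <- back_stage(bd$dx, cache$st1, 1L)
  dy <- dy * cache$red_mask
  brd <- conv3d_bwd_cpp(cache$xcat, cache$dcat, dy, p[["reduce.W"]], 1L, 1L, 0L)
  addg("reduce.W", brd$dw); addg("reduce.b", brd$db)
  g4 <- g %/% 4L; v4 <- g4^3
  dcc <- array(brd$dx, c(v4, 2L * c2, B))
  d_mov <- as.numeric(dcc[, seq_len(c2), , drop = FALSE])
  d_ref <- as.numeric(dcc[, c2 + seq_len(c2), , drop = FALSE])
  back_stem <- function(dtop, bch, prefix) {
    dtop <- dtop * bch$m2
    b2 <- conv3d_bwd_cpp(bch$r1, bch$d2, dtop, p[[paste0(prefix, ".c2.W")]], 3L, 2L, 1L)
    addg(paste0(prefix, ".c2.W"), b2$dw); addg(paste0(prefix, ".c2.b"), b2$db)
    d1 <- b2$dx * bch$m1
    b1 <- conv3d_bwd_cpp(bch$x, bch$d1, d1, p[[paste0(prefix, ".c1.W")]], 3L, 2L, 1L)
    addg(paste0(prefix, ".c1.W"), b1$dw); addg(paste0(prefix, ".c1.b"), b1$db)
  }
  s_mov <- if (cfg$share_stem) "stem" else "stem_mov"
  s_ref <- if (cfg$share_stem) "stem" else "stem_ref"
  back_stem(d_mov, cache$bm, s_mov)
  back_stem(d_ref, cache$br, s_ref)
  gr
}

loss_and_grad <- function(pred, target, loss, delta) {
  e <- pred - target
  n <- length(e)
  if (loss == "mse") {
    list(loss = mean(e^2), dpred = 2 * e / n)
  } else {
    a <- abs(e)
    l <- ifelse(a <= delta, 0.5 * e^2, delta * (a - 0.5 * delta))
    d <- ifelse(a <= delta, e, delta * sign(e))
    list(loss = mean(l), dpred = d / n)
  }
}

#' Train the translation regressor
#'
#' Minimises the regression loss between predicted and target translation
#' vectors (mm) with Adam, iterating over seeded shuffled minibatches.
#' Deterministic under a fixed config seed and single-threaded execution.
#'
#' @param samples a training set from [make_samples()].
#' @param config a [moco_config()]; its `grid` must match the one the samples
#'   were preprocessed at.
#' @param model optionally continue training an existing [build_regressor()]
#'   model instead of initialising a fresh one.
#' @param verbose print per-epoch loss.
#' @return a trained `moco_net`; `$history` holds the per-epoch mean training
#'   loss.
#' @export
train_regressor <- function(samples, config = moco_config(), model = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(samples, "moco_training_set"))
  n <- ncol(samples$mov)
  stop_if(n < 1, "no training samples")
  stop_if(samples$grid != config$grid,
          "samples were preprocessed at grid ", samples$grid,
          ", config expects ", config$grid)
  net <- model %||% build_regressor(config)
  adam_m <- lapply(net$params, function(x) x * 0)
  adam_v <- adam_m
  t_step <- 0L
  history <- net$history
  with_seed(child_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        mov <- as.numeric(samples$mov[, idx, drop = FALSE])
        ref <- as.numeric(samples$ref[, samples$ref_of[idx], drop = FALSE])
        fw <- net_forward(net, mov, ref, samples$frame_norm[idx], want_cache = TRUE)
        lg <- loss_and_grad(fw$pred, samples$target[, idx, drop = FALSE],
                            config$loss, config$huber_delta)
        stop_if(!is.finite(lg$loss),
                "training diverged (non-finite loss) at epoch ", ep)
        gr <- net_backward(net, fw$cache, lg$dpred)
        t_step <- t_step + 1L
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        for (nm in names(net$params)) {
          gmat <- gr[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gmat
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gmat^2
          mhat <- adam_m[[nm]] / (1 - b1^t_step)
          vhat <- adam_v[[nm]] / (1 - b2^t_step)
          net$params[[nm]] <- net$params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      history <- c(history, ep_loss / nb)
      if (verbose) message(sprintf("epoch %d/%d  loss %.4g", ep, config$epochs,
                                   ep_loss / nb))
    }
  })
  net$history <- history
  net$config <- config
  net
}

#' Predict a per-frame correction trace for a dynamic series
#'
#' Builds the summed-late-frame reference internally, preprocesses every
#' frame against it and runs the regressor. Frames contributing to the
#' reference are still individually predicted and corrected.
#'
#' @param model a trained `moco_net`.
#' @param series a [dynamic_series].
#' @param cutoff_s reference cutoff; defaults to the model config.
#' @return a [motion_trace] of predicted corrections (mm), clipped to the
#'   configured motion bound.
#' @export
predict_trace <- function(model, series, cutoff_s = NULL) {
  stopifnot(inherits(model, "moco_net"), inherits(series, "dynamic_series"))
  cfg <- model$config
  cutoff_s <- cutoff_s %||% cfg$cutoff_s
  ref <- build_reference(series, cutoff_s)
  nf <- n_frames(series)
  g <- cfg$grid
  mov <- matrix(0, g^3, nf)
  refv <- NULL
  for (i in seq_len(nf)) {
    pp <- preprocess_pair(get_frame(series, i), ref, series$spacing_mm, cfg)
    mov[, i] <- pp$mov
    if (is.null(refv)) refv <- as.numeric(pp$ref)
  }
  fnorm <- (seq_len(nf) - 1) / max(1L, nf - 1L)
  preds <- matrix(0, 3, nf)
  bs <- cfg$batch_size
  for (start in seq(1L, nf, by = bs)) {
    idx <- start:min(start + bs - 1L, nf)
    fw <- net_forward(model, as.numeric(mov[, idx, drop = FALSE]),
                      rep(refv, length(idx)), fnorm[idx])
    preds[, idx] <- fw$pred
  }
  preds <- pmin(pmax(preds, -cfg$max_motion_mm), cfg$max_motion_mm)
  motion_trace(t(preds), max_mm = cfg$max_motion_mm)
}

#' @export
predict.moco_net <- function(object, newdata, ...) {
  predict_trace(object, newdata, ...)
}
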