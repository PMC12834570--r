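#' Build per-frame training samples from dynamic cases
#'
#' Every frame of every case becomes one training sample: the preprocessed
#' moving frame, its case's preprocessed summed-late-frame reference, and the
#' target correction vector in mm. When two operator traces are given, a
#' seeded randomizer picks one per case. On top of the operator-derived
#' samples, `n_aug_per_case` bootstrap-augmented variants are created per
#' case: a trace drawn from `sampler` additionally displaces every frame (by
#' its inverse), and the target becomes the composed correction
#' (operator correction + sampled vector), so a corrupting displacement `d`
#' always has target `-d` relative to the aligned state. Augmented variants
#' rebuild their own reference from the re-corrupted series.
#'
#' @param cases list of cases; each a list with `series` (a
#'   [dynamic_series]), `traces` (one [motion_trace] or a list of per-operator
#'   traces), `case_id`, `site_id`, and optionally `phase`.
#' @param sampler a [fit_sampler()] result, or a named list of samplers keyed
#'   by phase (each case then draws from the sampler of its own phase);
#'   required when `n_aug_per_case > 0`.
#' @param n_aug_per_case augmented variants per case (default 0).
#' @param config a [moco_config()] controlling preprocessing grid and
#'   reference cutoff.
#' @param seed seed for operator choice and augmentation draws.
#' @param randomize_operator pick one operator trace at random per case
#'   (`TRUE`, the default); otherwise the first trace is used.
#' @return Object of class `moco_training_set`: preprocessed sample matrices
#'   (`mov` is `grid^3 x n`), per-case reference volumes (`ref`, with
#'   `ref_of` mapping samples to columns), `target` (3 x n, mm),
#'   `frame_norm`, `case_id`, `site_id`, `operator`, `augmented`.
#' @export
make_samples <- function(cases, sampler = NULL, n_aug_per_case = 0L,
                         config = moco_config(), seed = NULL,
                         randomize_operator = TRUE) {
  stop_if(length(cases) < 1, "no cases")
  stop_if(n_aug_per_case > 0 && is.null(sampler),
          "a sampler is required for augmentation")
  g <- config$grid
  frames_per_case <- vapply(cases, function(cs) n_frames(cs$series), 1L)
  n_total <- sum(frames_per_case) * (1L + n_aug_per_case)
  mov <- matrix(0, g^3, n_total)
  ref <- matrix(0, g^3, length(cases) * (1L + n_aug_per_case))
  target <- matrix(0, 3, n_total)
  frame <- integer(n_total); ref_of <- integer(n_total)
  frame_norm <- numeric(n_total)
  case_id <- character(n_total); site_id <- character(n_total)
  operator <- integer(n_total); aug_no <- integer(n_total)
  col <- 0L; rcol <- 0L
  with_seed(seed, {
    for (ci in seq_along(cases)) {
      cs <- cases[[ci]]
      series <- cs$series
      nf <- n_frames(series)
      traces <- cs$traces
      if (inherits(traces, "motion_trace")) traces <- list(traces)
      op <- if (length(traces) > 1L && randomize_operator)
        sample.int(length(traces), 1L) else 1L
      gt <- traces[[op]]
      stop_if(nrow(gt) != nf, "case ", cs$case_id %||% ci,
              ": trace rows do not match frame count")
      smp <- sampler
      if (is.list(sampler) && !inherits(sampler, "frame_motion_sampler")) {
        smp <- sampler[[cs$phase %||% "stress"]]
        stop_if(is.null(smp), "no sampler for phase '", cs$phase, "'")
      }
      aug_traces <- if (n_aug_per_case > 0)
        sample_traces(smp, n_aug_per_case) else list()
      for (v in 0:n_aug_per_case) {
        if (v == 0L) {
          sv <- series
          tgt <- gt
        } else {
          s_tr <- aug_traces[[v]]
          stop_if(nrow(s_tr) != nf, "sampled trace length does not match frames")
          sv <- apply_motion(series, invert_trace(s_tr))
          # composed corrections can exceed the single-trace bound
          tgt <- motion_trace(unclass(gt) + unclass(s_tr),
                              max_mm = 2 * attr(gt, "max_mm"))
        }
        refvol <- build_reference(sv, config$cutoff_s)
        rcol <- rcol + 1L
        for (f in seq_len(nf)) {
          pp <- preprocess_pair(get_frame(sv, f), refvol, sv$spacing_mm, config)
          col <- col + 1L
          mov[, col] <- pp$mov
          if (f == 1L) ref[, rcol] <- pp$ref
          target[, col] <- tgt[f, ]
          frame[col] <- f - 1L
          frame_norm[col] <- (f - 1L) / max(1L, nf - 1L)
          ref_of[col] <- rcol
          case_id[col] <- as.character(cs$case_id %||% ci)
          site_id[col] <- as.character(cs$site_id %||% NA)
          operator[col] <- op
          aug_no[col] <- v
        }
      }
    }
  })
  structure(list(
    mov = mov, ref = ref, ref_of = ref_of, target = target,
    frame_norm = frame_norm, frame = frame, case_id = case_id,
    site_id = site_id, operator = operator, augmented = aug_no > 0L,
    grid = g), class = "moco_training_set")
}

#' @export
print.moco_training_set <- function(x, ...) {
  cat(sprintf("<moco_training_set> %d samples (%d augmented) from %d cases, grid %d^3\n",
              ncol(x$mov), sum(x$augmented), length(unique(x$case_id)), x$grid))
  invisible(x)
}

#' Site-disjoint fold assignment
#'
#' Assigns whole sites to `k` folds so that no site ever spans two folds
#' (the external-validation constraint), balancing fold case counts with a
#' greedy largest-first heuristic: sites are sorted by descending case count
#' (ties shuffled by seed) and each is placed in the currently smallest fold.
#' The resulting case-count spread never exceeds the largest single-site
#' size.
#'
#' @param case_table data.frame with columns `case_id` and `site_id`.
#' @param k number of folds (default 5); must not exceed the site count.
#' @param seed seed for tie shuffling.
#' @return Object of class `fold_split`: data.frame `cases` (case_id,
#'   site_id, fold in 0..k-1) plus `site_fold` named map and `k`.
#' @export
split_by_site <- function(case_table, k = 5L, seed = NULL) {
  stop_if(!all(c("case_id", "site_id") %in% names(case_table)),
          "case_table needs case_id and site_id columns")
  stop_if(anyDuplicated(case_table$case_id) > 0, "duplicate case ids")
  sites <- table(as.character(case_table$site_id))
  stop_if(length(sites) < k, "fewer sites (", length(sites),
          ") than folds (", k, ")")
  ord <- with_seed(seed, {
    shuffled <- sample(names(sites))
    shuffled[order(-sites[shuffled])]
  })
  fold_sizes <- numeric(k)
  site_fold <- stats::setNames(integer(length(sites)), ord)
  for (s in ord) {
    f <- which.min(fold_sizes)
    site_fold[s] <- f - 1L
    fold_sizes[f] <- fold_sizes[f] + sites[[s]]
  }
  # refinement: move single sites from the fullest to the emptiest fold
  # whenever that shrinks the spread (folds stay non-empty)
  for (iter in seq_len(100L)) {
    hi <- which.max(fold_sizes); lo <- which.min(fold_sizes)
    gap <- fold_sizes[hi] - fold_sizes[lo]
    if (gap <= 1) break
    cand <- names(site_fold)[site_fold == hi - 1L]
    if (length(cand) < 2L) break
    w <- vapply(cand, function(s) sites[[s]], 0)
    ok <- w < gap
    if (!any(ok)) break
    pick <- cand[ok][which.min(abs(w[ok] - gap / 2))]
    new_sizes <- fold_sizes
    new_sizes[hi] <- new_sizes[hi] - sites[[pick]]
    new_sizes[lo] <- new_sizes[lo] + sites[[pick]]
    if (max(new_sizes) - min(new_sizes) >= gap) break
    site_fold[pick] <- lo - 1L
    fold_sizes <- new_sizes
  }
  cases <- data.frame(case_id = case_table$case_id,
                      site_id = as.character(case_table$site_id),
                      fold = site_fold[as.character(case_table$site_id)],
                      row.names = NULL)
  structure(list(cases = cases, site_fold = site_fold, k = as.integer(k)),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  sz <- table(factor(x$cases$fold, levels = 0:(x$k - 1)))
  cat(sprintf("<fold_split> %d cases, %d sites, %d folds (sizes: %s)\n",
              nrow(x$cases), length(x$site_fold), x$k,
              paste(sz, collapse = ", ")))
  invisible(x)
}

#' Site-wise k-fold cross-validation of the regressor
#'
#' For each fold: trains on all other folds (with bootstrap augmentation
#' from a sampler fitted to the training folds' traces), predicts the
#' held-out cases, and evaluates per-axis translation errors against the
#' ground-truth traces.
#'
#' @param cases list of cases as in [make_samples()] (single trace per case).
#' @param k number of folds.
#' @param config a [moco_config()].
#' @param n_aug_per_case augmented variants per training case.
#' @param seed master seed (drives splitting, augmentation and training).
#' @param phase phase label for the sampler fitted from training traces.
#' @return data.frame with one row per fold and axis (`fold`, `axis`,
#'   `avg_error_mm`, `max_error_mm`, `n_frames`), with a `summary` attribute
#'   holding mean and SD of the per-fold average errors per axis.
#' @export
crossval_evaluate <- function(cases, k = 5L, config = moco_config(),
                              n_aug_per_case = 0L, seed = 1L,
                              phase = "stress") {
  ct <- data.frame(
    case_id = vapply(seq_along(cases), function(i) as.character(cases[[i]]$case_id %||% i), ""),
    site_id = vapply(seq_along(cases), function(i) as.character(cases[[i]]$site_id %||% i), ""))
  split <- split_by_site(ct, k = k, seed = child_seed(seed, "split"))
  rows <- list()
  for (f in 0:(k - 1L)) {
    train_idx <- which(split$cases$fold != f)
    test_idx <- which(split$cases$fold == f)
    sampler <- if (n_aug_per_case > 0)
      fit_sampler(traces_to_table(cases[train_idx], phase), phase = phase)
    else NULL
    cfg <- config
    cfg$seed <- child_seed(seed, paste0("fold", f))
    ts <- make_samples(cases[train_idx], sampler, n_aug_per_case, cfg,
                       seed = child_seed(seed, paste0("aug", f)))
    model <- train_regressor(ts, cfg)
    gt_all <- NULL; pred_all <- NULL
    for (i in test_idx) {
      pr <- predict_trace(model, cases[[i]]$series)
      tr <- cases[[i]]$traces
      if (is.list(tr) && !inherits(tr, "motion_trace")) tr <- tr[[1]]
      gt_all <- rbind(gt_all, unclass(tr))
      pred_all <- rbind(pred_all, unclass(pr))
    }
    te <- translation_error(motion_trace(gt_all), motion_trace(pred_all))
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, axis = c("x", "y", "z"),
      avg_error_mm = te$avg_mm, max_error_mm = te$max_mm,
      n_frames = te$n)
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(c("x", "y", "z"), function(ax) {
    e <- out$avg_error_mm[out$axis == ax]
    data.frame(axis = ax, mean_avg_error_mm = mean(e), sd_avg_error_mm = stats::sd(e))
  }))
  attr(out, "summary") <- smry
  out
}

#' Collect case traces into a correction table
#'
#' Stacks the (first) per-case correction traces into the long-format
#' [correction_table()] a [fit_sampler()] expects, labelled as a single
#' operator.
#'
#' @param cases list of cases as in [make_samples()].
#' @param phase phase label for every row.
#' @return a [correction_table].
#' @export
traces_to_table <- function(cases, phase = "stress") {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    tr <- cs$traces
    if (is.list(tr) && !inherits(tr, "motion_trace")) tr <- tr[[1]]
    data.frame(case_id = as.character(cs$case_id %||% i),
               site_id = as.character(cs$site_id %||% i),
               phase = phase, frame = seq_len(nrow(tr)) - 1L, operator = 1L,
               tx_mm = tr[, 1], ty_mm = tr[, 2], tz_mm = tr[, 3])
  })
  correction_table(do.call(rbind, rows))
}
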