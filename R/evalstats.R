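#' Per-axis translation error between two motion traces
#'
#' For each axis the average error is `(1/N) * sum(sqrt((gt - pt)^2))` over
#' frames — the per-frame absolute deviation averaged — together with the
#' per-axis maximum absolute error. A true root-mean-square variant
#' (`sqrt(mean((gt - pt)^2))`) is also reported.
#'
#' @param gt,pred [motion_trace] objects of equal length (or plain `n x 3`
#'   matrices in mm).
#' @return Object of class `translation_error_report`: list with `avg_mm`,
#'   `max_mm`, `rmse_mm` (each named length-3 per axis) and `n`.
#' @export
translation_error <- function(gt, pred) {
  gt <- as.matrix(unclass(gt)); pred <- as.matrix(unclass(pred))
  stop_if(nrow(gt) != nrow(pred), "traces have different lengths")
  stop_if(nrow(gt) < 1, "need at least one frame")
  d <- abs(gt - pred)
  out <- list(avg_mm = stats::setNames(colMeans(d), c("x", "y", "z")),
              max_mm = stats::setNames(apply(d, 2, max), c("x", "y", "z")),
              rmse_mm = stats::setNames(sqrt(colMeans(d^2)), c("x", "y", "z")),
              n = nrow(gt))
  class(out) <- "translation_error_report"
  out
}

#' @export
print.translation_error_report <- function(x, ...) {
  cat(sprintf("translation error over %d frames (mm):\n", x$n))
  m <- rbind(average = x$avg_mm, max = x$max_mm, rmse = x$rmse_mm)
  print(round(m, 3))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Mean difference and half-width of the 95% limits of agreement,
#' `1.96 * SD(a - b)` (sample SD).
#'
#' @param a,b paired measurements, length >= 2.
#' @return list with `mean_diff`, `loa_half_width`, `n`.
#' @export
bland_altman <- function(a, b) {
  stop_if(length(a) != length(b), "a and b must be paired")
  stop_if(length(a) < 2, "need n >= 2")
  d <- a - b
  list(mean_diff = mean(d), loa_half_width = 1.96 * stats::sd(d), n = length(d))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the 45-degree line through the
#' origin: `CCC = 2 cov(a,b) / (var(a) + var(b) + (mean(a) - mean(b))^2)`
#' with population (1/n) moments, per Lin's original definition. The 95% CI
#' uses the Fisher z-transform with Lin's asymptotic standard error.
#'
#' @param a,b paired measurements, n >= 3, each with nonzero variance.
#' @param conf_level confidence level (default 0.95).
#' @return list with `ccc`, `ci` (length 2), `n`.
#' @export
lins_ccc <- function(a, b, conf_level = 0.95) {
  stop_if(length(a) != length(b), "a and b must be paired")
  n <- length(a)
  stop_if(n < 3, "need n >= 3")
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  stop_if(va == 0 || vb == 0, "zero variance")
  cab <- mean((a - ma) * (b - mb))
  ccc <- 2 * cab / (va + vb + (ma - mb)^2)
  r <- cab / sqrt(va * vb)
  u <- (ma - mb) / sqrt(sqrt(va * vb))
  # Lin's asymptotic variance of the z-transformed CCC
  se_z <- sqrt(((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                  2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                  ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (is.finite(se_z) && abs(ccc) < 1) {
    z <- atanh(ccc)
    ci <- tanh(c(z - zq * se_z, z + zq * se_z))
  } else {
    ci <- c(ccc, ccc)
  }
  list(ccc = ccc, ci = ci, n = n)
}

#' Compare two concordance correlation coefficients
#'
#' Fisher z-transform of each CCC; the difference is referred to a standard
#' normal with variance `1/(n1-3) + 1/(n2-3)` (independent samples).
#'
#' @param ccc1,ccc2 coefficients with `|ccc| < 1`.
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `z`, `p` (two-sided).
#' @export
compare_ccc <- function(ccc1, n1, ccc2, n2) {
  stop_if(abs(ccc1) >= 1 || abs(ccc2) >= 1,
          "|ccc| = 1: Fisher transform diverges")
  stop_if(n1 < 4 || n2 < 4, "need n >= 4")
  z <- (atanh(ccc1) - atanh(ccc2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pitman-Morgan test of equal variances for paired samples
#'
#' Tests `var(a) = var(b)` through the correlation between the pair sums and
#' differences: with `r = cor(a + b, a - b)`,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param a,b paired samples, n >= 3.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pitman_morgan <- function(a, b) {
  stop_if(length(a) != length(b), "a and b must be paired")
  n <- length(a)
  stop_if(n < 3, "need n >= 3")
  s <- a + b; d <- a - b
  vs <- stats::var(s); vd <- stats::var(d)
  stop_if(vs == 0 && vd == 0, "degenerate input: sums and differences constant")
  if (vs == 0 || vd == 0) {
    # cov(s, d) = var(a) - var(b) is exactly zero here: variances equal
    return(list(t = 0, df = n - 2, p = 1))
  }
  r <- stats::cor(s, d)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t = t, df = n - 2, p = 2 * stats::pt(-abs(t), n - 2))
}

orient_scores <- function(scores, orientation) {
  orientation <- match.arg(orientation, c("higher", "lower"))
  if (orientation == "lower") -scores else scores
}

# DeLong structural components: V10 per positive case, V01 per negative.
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), 0)
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong AUC with variance and confidence interval
#'
#' Area under the ROC curve as the Mann-Whitney statistic with half credit
#' for ties, after orienting the scores so that higher values indicate the
#' positive class; variance from DeLong's structural components; normal
#' 95% CI clipped to `[0, 1]`.
#'
#' Flow-based diagnostic scores use `orientation = "lower"`: flows are lower
#' in disease.
#'
#' @param scores numeric diagnostic scores.
#' @param labels 0/1 class labels (1 = positive/disease); both classes must
#'   be present.
#' @param orientation `"higher"` (default) or `"lower"`: which direction of
#'   the raw score indicates the positive class.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci`, `m` (positives), `n` (negatives).
#' @export
auc_delong <- function(scores, labels, orientation = "higher",
                       conf_level = 0.95) {
  stop_if(length(scores) != length(labels), "scores and labels must be paired")
  labels <- as.integer(labels)
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be 0/1")
  stop_if(length(unique(labels)) < 2, "both classes must be present")
  s <- orient_scores(scores, orientation)
  cp <- delong_components(s, labels)
  v <- 0
  if (cp$m > 1) v <- v + stats::var(cp$v10) / cp$m
  if (cp$n > 1) v <- v + stats::var(cp$v01) / cp$n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(cp$auc + c(-1, 1) * zq * sqrt(v), 0), 1)
  list(auc = cp$auc, var = v, ci = ci, m = cp$m, n = cp$n)
}

#' Paired DeLong comparison of two AUCs
#'
#' Both score vectors must be measured on the same cases. The difference in
#' AUCs is referred to a standard normal with variance from the paired
#' DeLong covariance of the structural components.
#'
#' @param scores1,scores2 paired score vectors.
#' @param labels 0/1 labels shared by both.
#' @param orientation as in [auc_delong()], applied to both score vectors.
#' @return list with `auc1`, `auc2`, `z`, `p` (two-sided), `flag`
#'   (`"zero_variance"` when the difference has no sampling variability, in
#'   which case `p = 1`).
#' @export
delong_compare <- function(scores1, scores2, labels, orientation = "higher") {
  stop_if(length(scores1) != length(scores2), "score vectors must be paired")
  labels <- as.integer(labels)
  stop_if(!all(labels %in% c(0L, 1L)), "labels must be 0/1")
  stop_if(length(unique(labels)) < 2, "both classes must be present")
  s1 <- orient_scores(scores1, orientation)
  s2 <- orient_scores(scores2, orientation)
  c1 <- delong_components(s1, labels)
  c2 <- delong_components(s2, labels)
  cov10 <- if (c1$m > 1) stats::cov(c1$v10, c2$v10) else 0
  cov01 <- if (c1$n > 1) stats::cov(c1$v01, c2$v01) else 0
  v1 <- (if (c1$m > 1) stats::var(c1$v10) else 0) / c1$m +
    (if (c1$n > 1) stats::var(c1$v01) else 0) / c1$n
  v2 <- (if (c2$m > 1) stats::var(c2$v10) else 0) / c2$m +
    (if (c2$n > 1) stats::var(c2$v01) else 0) / c2$n
  vd <- v1 + v2 - 2 * (cov10 / c1$m + cov01 / c1$n)
  dauc <- c1$auc - c2$auc
  if (vd <= 0) {
    return(list(auc1 = c1$auc, auc2 = c2$auc, z = 0, p = 1,
                flag = "zero_variance"))
  }
  z <- dauc / sqrt(vd)
  list(auc1 = c1$auc, auc2 = c2$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       flag = "ok")
}
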