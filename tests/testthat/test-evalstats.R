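test_that("translation errors follow the per-axis printed formula", {
  gt <- motion_trace(rbind(c(3, 0, 1), c(1, 0, -1)))
  pr <- motion_trace(rbind(c(0, 0, 1), c(0, 0, -1)))
  te <- translation_error(gt, pr)
  expect_equal(unname(te$avg_mm), c(2, 0, 0))
  expect_equal(unname(te$max_mm), c(3, 0, 0))
  expect_equal(unname(te$rmse_mm), c(sqrt(5), 0, 0))
  expect_true(all(unlist(translation_error(gt, gt)[c("avg_mm", "max_mm")]) == 0))
  # homogeneity of degree 1
  te2 <- translation_error(motion_trace(3 * unclass(gt)),
                           motion_trace(3 * unclass(pr)))
  expect_equal(te2$avg_mm, 3 * te$avg_mm)
  expect_equal(te2$max_mm, 3 * te$max_mm)
  expect_error(translation_error(gt, motion_trace(rbind(c(0, 0, 0)))),
               "different lengths")
})

test_that("Bland-Altman limits match the closed form", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a), list(mean_diff = 0, loa_half_width = 0, n = 4))
  ba <- bland_altman(c(1, 0), c(0, 1))   # differences {1, -1}
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_half_width, 1.96 * sqrt(2))
  ba2 <- bland_altman(a + 5, c(2, 1, 4, 3))
  ba3 <- bland_altman(a, c(2, 1, 4, 3))
  expect_equal(ba2$mean_diff, ba3$mean_diff + 5)
  expect_equal(ba2$loa_half_width, ba3$loa_half_width)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("Lin's CCC matches the direct formula with a sane CI", {
  expect_equal(lins_ccc(c(1, 2, 3), c(1, 2, 3))$ccc, 1)
  cc <- lins_ccc(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cc$ccc, 8 / 22)
  expect_equal(cc$ccc, lins_ccc(c(2, 4, 6), c(1, 2, 3))$ccc)  # symmetry
  set.seed(1)
  a <- rnorm(40); b <- 0.8 * a + rnorm(40, 0, 0.4) + 0.2
  cc2 <- lins_ccc(a, b)
  expect_true(cc2$ci[1] <= cc2$ccc && cc2$ccc <= cc2$ci[2])
  expect_lte(abs(cc2$ccc), abs(stats::cor(a, b)))   # attenuation
  expect_error(lins_ccc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("CCC comparison via Fisher z behaves as expected", {
  eq <- compare_ccc(0.5, 50, 0.5, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # the reported stress-flow agreement gap: p shrinks as n grows
  p_n <- vapply(c(30, 60, 120, 231), function(n)
    compare_ccc(0.943, n, 0.864, n)$p, 0)
  expect_true(all(diff(p_n) < 0))
  sw <- compare_ccc(0.864, 231, 0.943, 231)
  fw <- compare_ccc(0.943, 231, 0.864, 231)
  expect_equal(sw$z, -fw$z)
  expect_equal(sw$p, fw$p)
  expect_error(compare_ccc(1, 10, 0.5, 10), "diverges")
})

test_that("Pitman-Morgan equals the sums/differences correlation test", {
  set.seed(2)
  a <- rnorm(30)
  pm0 <- pitman_morgan(a, -a)   # equal variances by construction
  expect_equal(pm0$t, 0, tolerance = 1e-12)
  expect_equal(pm0$p, 1, tolerance = 1e-12)
  b <- 2 * scale(a)[, 1] + rnorm(30, 0, 0.3)
  pm <- pitman_morgan(a, b)
  oracle <- stats::cor.test(a + b, a - b)
  expect_equal(pm$t, unname(oracle$statistic))
  expect_equal(pm$p, oracle$p.value)
  expect_equal(pitman_morgan(a + 100, b - 7)$p, pm$p, tolerance = 1e-9)
  expect_equal(pitman_morgan(a, a)$p, 1)   # identical pairs: equal variances
  expect_error(pitman_morgan(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("DeLong AUC matches the pairwise win-count oracle and pROC", {
  perf <- auc_delong(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  half <- auc_delong(c(0.9, 0.4, 0.7, 0.6), c(1, 1, 0, 0))
  expect_equal(half$auc, 0.5)   # 2 wins out of 4 pairs
  set.seed(3)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.4)
  mine <- auc_delong(scores, labels)
  # win-count oracle
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  expect_equal(mine$auc, wins / (length(pos) * length(neg)))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(pr)))
  expect_equal(mine$var, as.numeric(pROC::var(pr)), tolerance = 1e-9)
  # orientation contract
  flip <- auc_delong(-scores, labels, orientation = "lower")
  expect_equal(flip$auc, mine$auc)
})

test_that("paired DeLong comparison agrees with pROC and handles ties", {
  set.seed(4)
  labels <- rep(c(1, 0), each = 8)
  s1 <- rnorm(16) + labels
  s2 <- rnorm(16) + 0.5 * labels
  same <- delong_compare(s1, s1, labels)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "zero_variance")
  cmp <- delong_compare(s1, s2, labels)
  skip_if_not_installed("pROC")
  r1 <- pROC::roc(labels, s1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(labels, s2, quiet = TRUE, direction = "<")
  or <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(cmp$z, unname(or$statistic), tolerance = 1e-9)
  expect_equal(cmp$p, or$p.value, tolerance = 1e-9)
})

test_that("paired DeLong z is consistent with a bootstrap standard error", {
  labels <- c(1, 1, 1, 0, 0, 0)
  s1 <- c(3.1, 2.0, 1.2, 1.5, 0.7, 0.2)
  s2 <- c(2.8, 1.1, 1.6, 1.9, 0.8, 0.9)
  cmp <- delong_compare(s1, s2, labels)
  auc_of <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  d_obs <- auc_of(s1, labels) - auc_of(s2, labels)
  set.seed(5)
  reps <- 20000
  d_boot <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    idx <- sample.int(6, replace = TRUE)
    l <- labels[idx]
    if (length(unique(l)) < 2) next
    d_boot[i] <- auc_of(s1[idx], l) - auc_of(s2[idx], l)
  }
  se_boot <- stats::sd(d_boot, na.rm = TRUE)
  se_delong <- abs(d_obs / cmp$z)
  expect_lt(abs(se_delong - se_boot) / se_boot, 0.3)
})
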