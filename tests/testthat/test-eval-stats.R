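test_that("AUC equals the pair-counting oracle, with ties counted one half", {
  set.seed(91)
  for (k in 1:25) {
    n <- sample(8:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(roc_auc(scores, labels)$auc, pair_auc(scores, labels))
  }
  # perfectly separated scores
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_true(r$ci[1] <= r$auc && r$ci[2] >= r$auc)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("label-independent scores give chance-level AUC with a covering CI", {
  set.seed(92)
  scores <- rnorm(2000)
  labels <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  r <- roc_auc(scores, labels)
  expect_true(r$ci[1] < 0.5 && r$ci[2] > 0.5)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("the Youden threshold maximizes J over an exhaustive sweep", {
  # separated toy: midpoint threshold with J = 1
  yt <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(yt$threshold, 0.5)
  expect_equal(yt$j, 1)
  # identical distributions: J ~ 0
  set.seed(93)
  s <- rep(runif(30), 2)
  l <- rep(c(TRUE, FALSE), each = 30)
  expect_lte(youden_threshold(s, l)$j, 0.15)
  # random sets: no candidate (including every observed score) beats it
  for (k in 1:20) {
    n <- sample(10:25, 1)
    scores <- round(runif(n), 2)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    yt <- youden_threshold(scores, labels)
    jfun <- function(th) {
      mean(scores[labels] >= th) + mean(scores[!labels] < th) - 1
    }
    expect_equal(yt$j, jfun(yt$threshold))
    cand <- c(scores, scores - 1e-6, scores + 1e-6, -1, 2)
    expect_true(all(vapply(cand, jfun, numeric(1)) <= yt$j + 1e-12))
  }
})

test_that("DeLong AUC comparison is degenerate-safe, antisymmetric and near a bootstrap oracle", {
  set.seed(94)
  labels <- rep(c(TRUE, FALSE), each = 20)
  a <- rnorm(40) + labels * 1.2
  b <- a * 0.6 + rnorm(40) * 0.8 + labels * 0.4
  self <- compare_auc(a, a, labels)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  ab <- compare_auc(a, b, labels)
  ba <- compare_auc(b, a, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # bootstrap reference for the two-sided p-value
  set.seed(95)
  nb <- 10000
  d0 <- ab$auc_a - ab$auc_b
  dstar <- replicate(nb, {
    idx <- sample.int(40, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    pair_auc(a[idx], labels[idx]) - pair_auc(b[idx], labels[idx])
  })
  dstar <- dstar[!is.na(dstar)]
  p_boot <- 2 * min(mean(dstar <= 0), mean(dstar >= 0))
  expect_lt(abs(ab$p - min(p_boot, 1)), 0.02)
})

test_that("sensitivity/specificity at a fixed threshold match the hand-built confusion matrix", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  ss <- sens_spec_at(scores, labels, 0.5)
  expect_equal(ss$sensitivity, 3 / 4)
  expect_equal(ss$specificity, 3 / 4)
  expect_identical(c(ss$tp, ss$fp, ss$tn, ss$fn), c(3L, 1L, 3L, 1L))
  # boundary is closed on the positive side
  expect_equal(sens_spec_at(c(0.5, 0.4), c(TRUE, FALSE), 0.5)$sensitivity, 1)
  # extremes
  expect_equal(sens_spec_at(scores, labels, 1.1)$sensitivity, 0)
  expect_equal(sens_spec_at(scores, labels, 1.1)$specificity, 1)
  expect_equal(sens_spec_at(scores, labels, -1)$sensitivity, 1)
  # Wilson CIs contain the estimate and live in [0, 1]
  for (th in c(0.25, 0.5, 0.75)) {
    ss <- sens_spec_at(scores, labels, th)
    expect_true(ss$sensitivity_ci[1] <= ss$sensitivity &&
                  ss$sensitivity >= 0 && ss$sensitivity_ci[2] >= ss$sensitivity)
    expect_true(all(c(ss$sensitivity_ci, ss$specificity_ci) >= 0 &
                      c(ss$sensitivity_ci, ss$specificity_ci) <= 1))
  }
})

test_that("weighted kappa matches the direct-formula value on a printed-style table", {
  expect_equal(weighted_kappa(c(1, 2, 3, 2, 1), c(1, 2, 3, 2, 1)), 1)
  # frozen oracle: 3x3 contingency table, linear weights, computed by
  # explicit summation over the table (see value derivation in comments)
  a <- rep(c(1, 1, 1, 2, 2, 2, 3, 3, 3), times = c(20, 5, 0, 3, 15, 2, 0, 4, 11))
  b <- rep(c(1, 2, 3, 1, 2, 3, 1, 2, 3), times = c(20, 5, 0, 3, 15, 2, 0, 4, 11))
  # po_w = 1 - sum(w*obs)/n with w = |i-j|/2; direct arithmetic:
  # disagreements: w=0.5 cells: 5+3+2+4 = 14; w=1 cells: 0+0 = 0
  # sum(w*obs) = 7; row marg = (25,20,15)/60, col marg = (23,24,13)/60
  # sum(w*exp) = [0.5*(25*24+20*23+20*13+15*24) + 1*(25*13+15*23)] / 60
  n <- 60
  swe <- (0.5 * (25 * 24 + 20 * 23 + 20 * 13 + 15 * 24) +
            1 * (25 * 13 + 15 * 23)) / n
  oracle <- 1 - 7 / swe
  expect_equal(weighted_kappa(a, b, "linear"), oracle)
  # independent large-sample ratings: kappa near 0
  set.seed(96)
  x <- sample(1:4, 4000, replace = TRUE)
  y <- sample(1:4, 4000, replace = TRUE)
  expect_lt(abs(weighted_kappa(x, y)), 0.05)
  # quadratic weighting differs from linear on imperfect agreement
  expect_false(isTRUE(all.equal(weighted_kappa(a, b, "linear"),
                                weighted_kappa(a, b, "quadratic"))))
})

test_that("group comparisons follow the classical tests", {
  set.seed(97)
  x <- rnorm(50)
  w <- group_compare(x, x + 0.001, "wilcoxon")
  expect_gt(w$p, 0.5)
  big <- group_compare(rnorm(400), rnorm(400) + 1, "wilcoxon")
  expect_lt(big$p, 1e-6)
  # 2x2 table {10,20; 30,5}: Pearson chi-square by hand formula
  va <- rep(c("x", "y"), c(10, 20))
  vb <- rep(c("x", "y"), c(30, 5))
  cs <- group_compare(va, vb, "chi_square")
  hand <- 65 * (10 * 5 - 20 * 30)^2 / (30 * 35 * 40 * 25)
  expect_equal(cs$statistic, hand)
  expect_error(group_compare(numeric(0), 1:3), "empty")
})

test_that("subgroup evaluation uses the stated age and MD boundary conventions", {
  truth <- fx_truth()
  set.seed(98)
  recs <- lapply(1:60, function(i) {
    sample_normal_field(if (i <= 30) 59.99 else 60, truth, id = i,
                        eye = if (i %% 2) "right" else "left")
  })
  # ensure exactly-60 lands in the >=60 stratum
  ages <- vapply(recs, function(r) r$age, numeric(1))
  labels <- rep(c(TRUE, FALSE), 30)
  scores <- runif(60) + labels * 0.5
  md <- c(rep(-6, 30), rep(-5.99, 30))
  out <- subgroup_eval(scores, labels, recs, md, threshold = 0.5)
  expect_identical(out$age$`<60`$n, sum(ages < 60))
  expect_identical(out$age$`>=60`$n, sum(ages >= 60))
  expect_identical(out$severity$`<=-6dB`$n, 30L)
  expect_identical(out$severity$`>-6dB`$n, 30L)
  expect_true(all(c("left", "right") %in% names(out$eye)))
  # a single-class stratum is flagged, not failed
  out2 <- subgroup_eval(scores, rep(c(TRUE, FALSE), each = 30), recs,
                        md, 0.5)
  expect_identical(out2$severity$`<=-6dB`$flag, "single_class")
})
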