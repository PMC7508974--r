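#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is computed from the rank (Mann-Whitney) statistic with the usual
#' tie correction; the 95% CI uses DeLong's variance estimate (via pROC).
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels logical (or 0/1) disease labels.
#' @param conf.level confidence level (default 0.95).
#' @return List with `auc`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf.level = 0.95) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = conf.level, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(max(0, ci[1]), min(1, ci[3])),
       n_pos = sum(labels), n_neg = sum(!labels))
}

#' Youden-optimal operating threshold
#'
#' Sweeps the midpoints between adjacent distinct scores (plus sentinels
#' below and above all scores) and returns the threshold maximizing
#' J = sensitivity + specificity - 1, with a positive call at
#' score >= threshold. Ties in J resolve to the threshold with the higher
#' specificity (i.e. the larger threshold).
#'
#' @inheritParams roc_auc
#' @return List with `threshold` and `j`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  j <- vapply(cand, function(th) {
    mean(scores[labels] >= th) + mean(scores[!labels] < th) - 1
  }, numeric(1))
  best <- max(j)
  # among maximizers prefer higher specificity = larger threshold
  th <- max(cand[j >= best - 1e-12])
  list(threshold = th, j = best)
}

#' DeLong comparison of two AUCs
#'
#' Paired DeLong Z-test for correlated ROC curves (the two score vectors
#' are evaluated on the same records); an unpaired variant is available
#' for independent samples. A degenerate comparison with zero variance
#' and zero AUC difference (e.g. a score set against itself) returns
#' z = 0, p = 1.
#'
#' @param scores_a,scores_b score vectors.
#' @param labels disease labels (for `paired = TRUE`, shared; otherwise
#'   a list of two label vectors).
#' @param paired logical, default `TRUE`.
#' @return List with `z`, `p` (two-sided), `auc_a`, `auc_b`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, paired = TRUE) {
  if (paired) {
    labels <- as.logical(labels)
    if (length(scores_a) != length(scores_b) ||
        length(scores_a) != length(labels)) {
      stop("paired comparison needs equal-length scores and labels",
           call. = FALSE)
    }
    ra <- pROC::roc(labels, scores_a, levels = c(FALSE, TRUE),
                    direction = "<", quiet = TRUE)
    rb <- pROC::roc(labels, scores_b, levels = c(FALSE, TRUE),
                    direction = "<", quiet = TRUE)
    if (isTRUE(all.equal(scores_a, scores_b))) {
      return(list(z = 0, p = 1, auc_a = as.numeric(pROC::auc(ra)),
                  auc_b = as.numeric(pROC::auc(rb))))
    }
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  } else {
    stopifnot(is.list(labels), length(labels) == 2)
    ra <- pROC::roc(as.logical(labels[[1]]), scores_a,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    rb <- pROC::roc(as.logical(labels[[2]]), scores_b,
                    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    tst <- suppressWarnings(
      pROC::roc.test(ra, rb, method = "delong", paired = FALSE))
  }
  z <- as.numeric(tst$statistic)
  p <- as.numeric(tst$p.value)
  if (!is.finite(z)) { z <- 0; p <- 1 }
  list(z = z, p = p, auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)))
}

wilson_ci <- function(k, n, conf.level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Sensitivity and specificity at a fixed threshold
#'
#' A positive call is score >= threshold (closed on the positive side).
#' Confidence intervals are Wilson score intervals.
#'
#' @inheritParams roc_auc
#' @param threshold operating threshold fixed upstream (e.g. by
#'   [youden_threshold()] on validation data).
#' @return List with `sensitivity`, `specificity`, their `*_ci`, and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec_at <- function(scores, labels, threshold, conf.level = 0.95) {
  labels <- as.logical(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels); fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels); fp <- sum(pos & !labels)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sensitivity_ci = wilson_ci(tp, tp + fn, conf.level),
       specificity_ci = wilson_ci(tn, tn + fp, conf.level),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Weighted kappa agreement
#'
#' Cohen's kappa with linear disagreement weights by default (quadratic
#' selectable), for ordered category scales such as the five probability
#' levels.
#'
#' @param ratings_a,ratings_b integer/factor ratings on the same ordered
#'   scale.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param n_levels number of scale levels; defaults to the observed range.
#' @return Scalar kappa.
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           weights = c("linear", "quadratic"),
                           n_levels = NULL) {
  weights <- match.arg(weights)
  a <- as.integer(factor(ratings_a, levels = sort(unique(c(ratings_a, ratings_b)))))
  b <- as.integer(factor(ratings_b, levels = sort(unique(c(ratings_a, ratings_b)))))
  if (length(a) != length(b)) stop("rating scales mismatch", call. = FALSE)
  k <- if (is.null(n_levels)) max(a, b) else n_levels
  obs <- matrix(0, k, k)
  for (i in seq_along(a)) obs[a[i], b[i]] <- obs[a[i], b[i]] + 1
  obs <- obs / sum(obs)
  exp_ <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weights == "linear") d / (k - 1) else (d / (k - 1))^2
  1 - sum(w * obs) / sum(w * exp_)
}

#' Two-group comparison
#'
#' Wilcoxon rank-sum for numerical data or a chi-square test for
#' categorical data, two-sided (Wilcoxon uses the normal approximation
#' with continuity correction when ties are present; chi-square is the
#' classical Pearson test without continuity correction so it matches the
#' textbook formula).
#'
#' @param values_a,values_b the two samples. For `kind = "chi_square"`,
#'   two vectors of category labels.
#' @param kind `"wilcoxon"` or `"chi_square"`.
#' @return List with `statistic` and `p`.
#' @export
group_compare <- function(values_a, values_b,
                          kind = c("wilcoxon", "chi_square")) {
  kind <- match.arg(kind)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  if (kind == "wilcoxon") {
    tst <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  } else {
    tab <- table(group = rep(c("a", "b"), c(length(values_a),
                                            length(values_b))),
                 value = c(as.character(values_a), as.character(values_b)))
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  list(statistic = as.numeric(tst$statistic), p = tst$p.value)
}

#' Subgroup diagnostic evaluation at a fixed threshold
#'
#' Stratifies by eye (left vs right), age group (<60 vs >=60 years;
#' exactly 60 falls in the older stratum) and severity (MD > -6 dB vs
#' MD <= -6 dB; exactly -6 falls in the more severe stratum), reporting
#' AUC/sensitivity/specificity per stratum at the same threshold plus the
#' paired-strata AUC comparison. A stratum with a single class is flagged,
#' not failed.
#'
#' @param scores,labels scores and disease labels.
#' @param records list of `vf_record`s (for eye and age).
#' @param md per-record mean deviation values, dB.
#' @param threshold fixed operating threshold.
#' @return Named list of stratifications, each a list of per-stratum
#'   reports (`auc`, `ci`, `sensitivity`, `specificity`, `n`, `flag`) and
#'   an `auc_comparison` (z, p) when both strata are evaluable.
#' @export
subgroup_eval <- function(scores, labels, records, md, threshold) {
  labels <- as.logical(labels)
  eye <- vapply(records, function(r) r$eye, character(1))
  age <- vapply(records, function(r) r$age, numeric(1))
  strat <- list(
    eye = list(left = eye == "left", right = eye == "right"),
    age = list(`<60` = age < 60, `>=60` = age >= 60),
    severity = list(`>-6dB` = md > -6, `<=-6dB` = md <= -6)
  )
  out <- list()
  for (sn in names(strat)) {
    rep_s <- list()
    evaluable <- logical(0)
    for (gn in names(strat[[sn]])) {
      sel <- strat[[sn]][[gn]]
      one_class <- !any(labels[sel]) || all(labels[sel]) || sum(sel) == 0
      if (one_class) {
        rep_s[[gn]] <- list(n = sum(sel), flag = "single_class")
        evaluable <- c(evaluable, FALSE)
      } else {
        ra <- roc_auc(scores[sel], labels[sel])
        ss <- sens_spec_at(scores[sel], labels[sel], threshold)
        rep_s[[gn]] <- c(ra, ss[c("sensitivity", "specificity")],
                         list(n = sum(sel), flag = "ok"))
        evaluable <- c(evaluable, TRUE)
      }
    }
    if (all(evaluable)) {
      g <- names(strat[[sn]])
      s1 <- strat[[sn]][[g[1]]]; s2 <- strat[[sn]][[g[2]]]
      rep_s$auc_comparison <- compare_auc(
        scores[s1], scores[s2],
        labels = list(labels[s1], labels[s2]), paired = FALSE)[c("z", "p")]
    }
    out[[sn]] <- rep_s
  }
  out
}
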