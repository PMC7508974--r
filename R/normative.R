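#' @title Probability category levels
#' @description Category labels for deviation probability maps, ordered from
#'   least to most severe. A location printed "<1%" has a deviation seen in
#'   fewer than 1% of age-similar normal eyes.
#' @export
vf_categories <- function() c(">5%", "<5%", "<2%", "<1%", "<0.5%")

tail_probs <- c(0.05, 0.02, 0.01, 0.005)

#' Construct a visual-field record
#'
#' One eye's 24-2 test: age, laterality, the 52 measured sensitivities in dB
#' (active-location order of [vf_layout()]), and the reliability indices
#' used for exclusion (fixation losses as a count over trials, false-positive
#' and false-negative response rates).
#'
#' @param id record identifier.
#' @param eye `"right"` or `"left"`.
#' @param age age in years.
#' @param sensitivities numeric, length 52, in `[0, 50]` dB.
#' @param fl_num,fl_den fixation losses, e.g. 2 over 13.
#' @param fp,fn false-positive and false-negative rates in `[0, 1]`.
#' @param label `"glaucoma"`, `"non_glaucoma"` or `"unknown"`.
#' @param archetype optional simulator archetype name.
#' @return An object of class `vf_record`.
#' @export
vf_record <- function(id, eye, age, sensitivities, fl_num = 0, fl_den = 13,
                      fp = 0, fn = 0, label = "unknown", archetype = NA_character_) {
  eye <- match.arg(eye, c("right", "left"))
  label <- match.arg(label, c("glaucoma", "non_glaucoma", "unknown"))
  sensitivities <- as.numeric(sensitivities)
  if (length(sensitivities) != 52L) {
    stop("`sensitivities` must have 52 values", call. = FALSE)
  }
  if (any(!is.finite(sensitivities)) ||
      any(sensitivities < 0) || any(sensitivities > 50)) {
    stop("sensitivities must be finite and within [0, 50] dB", call. = FALSE)
  }
  if (fp < 0 || fp > 1 || fn < 0 || fn > 1 || fl_num < 0 || fl_den <= 0) {
    stop("reliability indices out of range", call. = FALSE)
  }
  structure(
    list(id = id, eye = eye, age = as.numeric(age),
         sensitivities = sensitivities,
         fl_num = as.numeric(fl_num), fl_den = as.numeric(fl_den),
         fp = as.numeric(fp), fn = as.numeric(fn),
         label = label, archetype = archetype),
    class = "vf_record"
  )
}

#' @export
print.vf_record <- function(x, ...) {
  cat(sprintf("VF record %s: %s eye, age %.0f, label %s, mean sens %.1f dB\n",
              x$id, x$eye, x$age, x$label, mean(x$sensitivities)))
  invisible(x)
}

#' Fit a normative sensitivity model from a non-glaucoma cohort
#'
#' Per active location, sensitivity is regressed linearly on age
#' (reference age 45 y), giving the location's mean-at-reference, age slope
#' and residual spread. Probability cutoffs at the 5/2/1/0.5% tails are
#' empirical residual quantiles: for total deviation (TD) from the raw
#' residuals, for pattern deviation (PD) from general-height-corrected
#' residuals, which is how normative databases for perimetry are
#' conventionally built.
#'
#' @param cohort list of `vf_record`s, all labelled non-glaucoma (at least
#'   100 records spanning at least 30 years of age).
#' @param sd_floor lower clamp on the per-location residual SD in dB
#'   (default 0.5); a degenerate cohort that hits the floor raises a warning.
#' @return An object of class `vf_normative`: per-location `mean45`,
#'   `slope` (dB/year, clamped <= 0), `sd` (dB), and 4-column cutoff
#'   matrices `td_cutoffs`, `pd_cutoffs` (columns 5%, 2%, 1%, 0.5%,
#'   strictly decreasing).
#' @export
fit_normative <- function(cohort, sd_floor = 0.5) {
  stopifnot(is.list(cohort), length(cohort) > 0)
  ages <- vapply(cohort, function(r) r$age, numeric(1))
  if (length(cohort) < 100) {
    stop("normative fit needs at least 100 records", call. = FALSE)
  }
  if (diff(range(ages)) < 30) {
    stop("normative fit needs an age range of at least 30 years",
         call. = FALSE)
  }
  S <- t(vapply(cohort, function(r) r$sensitivities, numeric(52)))
  a <- ages - 45
  X <- cbind(1, a)
  beta <- solve(crossprod(X), crossprod(X, S))  # 2 x 52
  mean45 <- beta[1, ]
  slope <- pmin(beta[2, ], 0)
  resid <- S - X %*% beta
  sd_hat <- apply(resid, 2, stats::sd)
  if (any(sd_hat < sd_floor)) {
    warning(sprintf("residual SD below %.2f dB at %d location(s); clamped",
                    sd_floor, sum(sd_hat < sd_floor)))
    sd_hat <- pmax(sd_hat, sd_floor)
  }
  td_cut <- t(apply(resid, 2, stats::quantile, probs = tail_probs,
                    names = FALSE))
  gh <- apply(resid, 1, general_height)
  pd_resid <- resid - gh
  pd_cut <- t(apply(pd_resid, 2, stats::quantile, probs = tail_probs,
                    names = FALSE))
  enforce_dec <- function(m) {
    # empirical quantiles can tie in tiny cohorts; nudge to keep them
    # strictly decreasing with tail probability
    t(apply(m, 1, function(v) cummin(v) - (1e-9 * seq_along(v))))
  }
  structure(
    list(mean45 = mean45, slope = slope, sd = sd_hat,
         td_cutoffs = enforce_dec(td_cut), pd_cutoffs = enforce_dec(pd_cut),
         reference_age = 45, n = length(cohort)),
    class = "vf_normative"
  )
}

#' @export
print.vf_normative <- function(x, ...) {
  cat(sprintf(
    "Normative model (n = %d): mean sens at 45 y %.1f-%.1f dB, slope %.3f-%.3f dB/y\n",
    x$n, min(x$mean45), max(x$mean45), min(x$slope), max(x$slope)))
  invisible(x)
}

#' Age-expected sensitivities under a normative model
#'
#' @param model a `vf_normative` (or any list with `mean45`, `slope`).
#' @param age age in years.
#' @return Numeric vector of length 52.
#' @export
expected_sensitivity <- function(model, age) {
  model$mean45 + model$slope * (age - 45)
}

#' Total deviation map
#'
#' TD is the measured sensitivity minus the age-expected normal value at
#' each location: `td_i = s_i - (mean45_i + slope_i * (age - 45))`.
#'
#' @param record a `vf_record`.
#' @param model a `vf_normative`.
#' @return Numeric vector of length 52 (dB).
#' @export
total_deviation <- function(record, model) {
  stopifnot(inherits(record, "vf_record"))
  if (length(model$mean45) != length(record$sensitivities)) {
    stop("record and model layouts disagree", call. = FALSE)
  }
  record$sensitivities - expected_sensitivity(model, record$age)
}

#' General height
#'
#' The overall elevation or depression of the field, estimated as the
#' 7th-highest TD value of the 52 (roughly the 85th percentile of the best
#' locations) — the conventional Humphrey estimator. Subtracting it from TD
#' gives pattern deviation, which removes diffuse loss such as cataract.
#'
#' @param td numeric TD vector of length 52.
#' @return Scalar dB.
#' @export
general_height <- function(td) {
  if (length(td) != 52L) stop("`td` must have 52 values", call. = FALSE)
  sort(td, decreasing = TRUE)[7]
}

#' Five-level probability category of a deviation value
#'
#' Categories follow the printed probability symbols: a value at or above
#' the 5% cutoff is ">5%"; otherwise the most severe category whose cutoff
#' the value falls strictly below. A value exactly equal to a cutoff
#' resolves to the less severe category (strict "<", matching the printed
#' labels).
#'
#' @param value deviation value(s), dB.
#' @param cutoffs 4 strictly decreasing dB cutoffs (5%, 2%, 1%, 0.5% tails).
#' @return Integer code(s) 0..4; 0 = ">5%", 4 = "<0.5%". Use
#'   `vf_categories()[code + 1]` for labels.
#' @export
probability_category <- function(value, cutoffs) {
  if (length(cutoffs) != 4L || any(diff(cutoffs) >= 0)) {
    stop("`cutoffs` must be 4 strictly decreasing values", call. = FALSE)
  }
  # code = number of cutoffs the value falls strictly below
  code <- rowSums(outer(value, cutoffs, "<"))
  as.integer(code)
}

#' Deviation maps for one record
#'
#' Computes TD, general height, PD = TD - GH, and the per-location 5-level
#' probability categories of both maps under the model's empirical cutoffs.
#'
#' @param record a `vf_record`.
#' @param model a `vf_normative`.
#' @return An object of class `vf_deviation`: list with `td`, `gh`, `pd`,
#'   `td_cat`, `pd_cat` (integer codes 0..4, see [probability_category()]).
#' @export
deviation_maps <- function(record, model) {
  td <- total_deviation(record, model)
  gh <- general_height(td)
  pd <- td - gh
  td_cat <- vapply(seq_along(td), function(i) {
    probability_category(td[i], model$td_cutoffs[i, ])
  }, integer(1))
  pd_cat <- vapply(seq_along(pd), function(i) {
    probability_category(pd[i], model$pd_cutoffs[i, ])
  }, integer(1))
  structure(list(td = td, gh = gh, pd = pd,
                 td_cat = td_cat, pd_cat = pd_cat),
            class = "vf_deviation")
}
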