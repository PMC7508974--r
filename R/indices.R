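#' Mean deviation
#'
#' The variance-weighted mean of the total-deviation map,
#' `MD = sum(w_i td_i) / sum(w_i)` with `w_i = 1 / SD_i^2`, so locations
#' with tighter normative spread count more. Negative MD means overall
#' depression relative to age-similar normals.
#'
#' @param td TD vector of length 52, dB.
#' @param model a `vf_normative` (supplies the per-location SDs).
#' @return Scalar dB.
#' @export
mean_deviation <- function(td, model) {
  if (length(td) != length(model$sd)) {
    stop("td and model layouts disagree", call. = FALSE)
  }
  w <- 1 / model$sd^2
  sum(w * td) / sum(w)
}

#' Pattern standard deviation
#'
#' A weighted dispersion of TD about MD:
#' `PSD = sqrt( N/(N-1) * sum(w_i (td_i - MD)^2) / sum(w_i) )` with
#' `w_i = 1 / SD_i^2` and N = 52. With equal weights this reduces to the
#' ordinary sample standard deviation of TD. PSD is near zero for uniform
#' (diffuse) loss and grows with localized irregularity.
#'
#' @param td TD vector of length 52, dB.
#' @param md the MD computed from the same TD map.
#' @param model a `vf_normative`.
#' @return Scalar dB, non-negative.
#' @export
pattern_standard_deviation <- function(td, md, model) {
  n <- length(td)
  if (n < 2) stop("PSD needs at least 2 locations", call. = FALSE)
  if (n != length(model$sd)) {
    stop("td and model layouts disagree", call. = FALSE)
  }
  w <- 1 / model$sd^2
  sqrt(n / (n - 1) * sum(w * (td - md)^2) / sum(w))
}

#' Simplified visual field index
#'
#' A percent-of-normal summary of visual function: 100% for a perfect
#' age-adjusted field, 0% for a perimetrically blind field. Each location
#' contributes a function score `f_i = clamp(1 + dev_i / expected_i, 0, 1)`
#' where `expected_i` is the age-expected sensitivity and `dev_i` is the
#' PD value when MD > -20 dB (so diffuse cataract-like loss is discounted)
#' and the TD value in advanced loss (MD <= -20 dB). A location whose
#' deviation is within normal limits (category ">5%" under the model's
#' cutoffs) scores 1 outright, so measurement noise at normal locations
#' does not erode the index. Scores are averaged
#' with centre weights that decay with eccentricity, reflecting the central
#' field's dominant contribution to visual function. The proprietary VFI
#' formula is unpublished, so this index is an explicitly simplified
#' convention of this package; outputs label it `vfi_simplified`.
#'
#' @param td,pd deviation maps, length 52.
#' @param md mean deviation of the same record, dB.
#' @param model a `vf_normative`.
#' @param age age in years (for the expected sensitivities).
#' @param layout a `vf_layout` (for eccentricities).
#' @return Percent in `[0, 100]`.
#' @export
visual_field_index <- function(td, pd, md, model, age, layout = vf_layout()) {
  stopifnot(length(td) == 52, length(pd) == 52)
  expected <- pmax(expected_sensitivity(model, age), 1e-6)
  use_pd <- md > -20
  dev <- if (use_pd) pd else td
  f <- pmin(pmax(1 + dev / expected, 0), 1)
  if (!is.null(model$td_cutoffs)) {
    cuts <- if (use_pd) model$pd_cutoffs else model$td_cutoffs
    normal <- vapply(seq_along(dev), function(i) {
      probability_category(dev[i], cuts[i, ]) == 0L
    }, logical(1))
    f[normal] <- 1
  }
  a <- layout$locations[layout$active, ]
  ecc <- sqrt(a$x^2 + a$y^2)
  cw <- exp(-(ecc / 15)^2)  # centre-weighted, ~1 at fixation
  100 * sum(cw * f) / sum(cw)
}

#' Global indices for one record
#'
#' @param record a `vf_record`.
#' @param model a `vf_normative`.
#' @param layout a `vf_layout`.
#' @return List with `md`, `psd`, `vfi_simplified`, `gh` and the
#'   `vf_deviation` maps under `maps`.
#' @export
global_indices <- function(record, model, layout = vf_layout()) {
  maps <- deviation_maps(record, model)
  md <- mean_deviation(maps$td, model)
  psd <- pattern_standard_deviation(maps$td, md, model)
  vfi <- visual_field_index(maps$td, maps$pd, md, model, record$age, layout)
  list(md = md, psd = psd, vfi_simplified = vfi, gh = maps$gh, maps = maps)
}

#' Reliability filter
#'
#' A record fails when fixation losses exceed 2/13 (strictly, as a
#' fraction, so denominators other than 13 are allowed), or the
#' false-positive rate exceeds 15%, or the false-negative rate exceeds
#' 25%. Boundary values pass.
#'
#' @param record a `vf_record` with reliability fields.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   the criteria that fired, empty when passing).
#' @export
passes_reliability <- function(record) {
  stopifnot(inherits(record, "vf_record"))
  need <- c("fl_num", "fl_den", "fp", "fn")
  if (any(vapply(record[need], function(v) is.null(v) || is.na(v), logical(1)))) {
    stop("reliability fields missing", call. = FALSE)
  }
  reasons <- character(0)
  if (record$fl_num / record$fl_den > 2 / 13) {
    reasons <- c(reasons, "fixation_losses")
  }
  if (record$fp > 0.15) reasons <- c(reasons, "false_positives")
  if (record$fn > 0.25) reasons <- c(reasons, "false_negatives")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
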