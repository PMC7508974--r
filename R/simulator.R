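#' Ground-truth normative parameters for simulation
#'
#' The generative model behind the simulator: per-location mean sensitivity
#' at the 45-year reference, an ageing slope, and between-subject spread,
#' all smooth functions of eccentricity chosen to resemble published
#' white-on-white normative data (central points near 33 dB, roughly
#' -0.06 dB/year decline, spread growing from ~1.4 dB centrally to
#' ~2.5 dB at the rim).
#'
#' @param layout a `vf_layout`.
#' @return A list with `mean45`, `slope`, `sd` (length 52), usable wherever
#'   a fitted `vf_normative` supplies those fields.
#' @export
normative_truth <- function(layout = vf_layout()) {
  a <- layout$locations[layout$active, ]
  ecc <- sqrt(a$x^2 + a$y^2)
  list(
    mean45 = 33.5 - 0.09 * ecc,
    slope = rep(-0.06, length(ecc)),
    sd = 1.2 + 0.05 * ecc
  )
}

#' Simulation configuration
#'
#' @param n_records number of records to draw.
#' @param class_mix named proportions over the archetypes
#'   (normal, arcuate_sup, arcuate_inf, nasal_step, paracentral, advanced,
#'   cataract_diffuse, hemianopia, myopia_rim, preperimetric); must sum
#'   to 1.
#' @param severity_range defect depth range in dB (uniform draw).
#' @param age_range age range in years (uniform draw).
#' @param noise_sd per-location measurement noise SD in dB.
#' @param seed integer seed governing the whole cohort.
#' @return A `vf_sim_config` list.
#' @export
sim_config <- function(n_records = 1000,
                       class_mix = c(normal = 0.35, arcuate_sup = 0.10,
                                     arcuate_inf = 0.10, nasal_step = 0.08,
                                     paracentral = 0.07, advanced = 0.08,
                                     cataract_diffuse = 0.07,
                                     hemianopia = 0.04, myopia_rim = 0.06,
                                     preperimetric = 0.05),
                       severity_range = c(4, 16),
                       age_range = c(25, 80),
                       noise_sd = 1.0,
                       seed = 1L) {
  stopifnot(n_records >= 0, noise_sd > 0, all(class_mix >= 0))
  if (length(class_mix) == 0 || sum(class_mix) == 0) {
    stop("class mix is empty", call. = FALSE)
  }
  bad <- setdiff(names(class_mix), vf_archetypes())
  if (length(bad)) {
    stop("unknown archetype(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class mix proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), class_mix = class_mix,
                 severity_range = severity_range, age_range = age_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "vf_sim_config")
}

#' Archetype names understood by the simulator
#' @return Character vector.
#' @export
vf_archetypes <- function() {
  c("normal", "arcuate_sup", "arcuate_inf", "nasal_step", "paracentral",
    "advanced", "cataract_diffuse", "hemianopia", "myopia_rim",
    "preperimetric")
}

glaucoma_archetypes <- function() {
  c("arcuate_sup", "arcuate_inf", "nasal_step", "paracentral", "advanced",
    "preperimetric")
}

#' Sample one normal (non-glaucomatous) field
#'
#' Sensitivities are the age-expected means plus a shared subject-level
#' height offset (1 dB SD, the source of general-height variation) plus
#' independent per-location noise at the model's between-subject spread
#' plus measurement noise. Reliability indices are drawn so roughly 90%
#' of records pass the reliability filter.
#'
#' @param age age in years.
#' @param model a `vf_normative` or [normative_truth()] list.
#' @param id record id.
#' @param eye `"right"` or `"left"`.
#' @param noise_sd measurement noise SD, dB.
#' @return A `vf_record` labelled `non_glaucoma`. Uses the current RNG
#'   state; seed it for reproducibility.
#' @export
sample_normal_field <- function(age, model, id = "sim", eye = "right",
                                noise_sd = 1.0) {
  n <- length(model$mean45)
  height <- stats::rnorm(1, 0, 1.0)
  s <- expected_sensitivity(model, age) + height +
    stats::rnorm(n, 0, model$sd) + stats::rnorm(n, 0, noise_sd)
  s <- pmin(pmax(s, 0), 50)
  vf_record(
    id = id, eye = eye, age = age, sensitivities = s,
    fl_num = stats::rbinom(1, 13, 0.06), fl_den = 13,
    fp = stats::rbeta(1, 1.5, 30), fn = stats::rbeta(1, 1.5, 25),
    label = "non_glaucoma", archetype = "normal"
  )
}

# Fixed location-sets for the defect archetypes, in the canonical
# right-eye frame. Weights: 1 in the mask core, 0.5 on the mask boundary
# (members with a lattice neighbour outside the mask), giving a smooth
# half-depth falloff at the rim of each defect.
archetype_mask <- function(archetype, layout = vf_layout(),
                           side = 1, hemi = 1) {
  a <- layout$locations[layout$active, ]
  xc <- if (layout$eye == "left") -a$x else a$x
  ecc <- sqrt(xc^2 + a$y^2)
  members <- switch(archetype,
    arcuate_sup = (a$y > 0 & ecc >= 9 & ecc <= 22 & xc <= 15),
    arcuate_inf = (a$y < 0 & ecc >= 9 & ecc <= 22 & xc <= 15),
    nasal_step = (xc <= -15 & sign(a$y) == hemi),
    paracentral = (ecc <= 9.5 & sign(a$y) == hemi & sign(xc) == side),
    advanced = ((ecc >= 9 & ecc <= 22 & xc <= 15) | xc <= -15),
    cataract_diffuse = rep(TRUE, nrow(a)),
    hemianopia = (sign(xc) == side),
    myopia_rim = a$edge,
    preperimetric = (a$y > 0 & ecc >= 9 & ecc <= 22 & xc <= 15),
    stop("unknown archetype: ", archetype, call. = FALSE)
  )
  w <- as.numeric(members)
  if (archetype != "cataract_diffuse") {
    adj <- vf_adjacency(layout)
    boundary <- members & apply(adj, 1, function(nb) any(nb & !members))
    w[boundary] <- 0.5
  }
  w
}

#' Superimpose a defect archetype on a record
#'
#' Subtracts a fixed spatial mask scaled by `severity` (dB at the mask
#' core, half depth at the mask boundary) from the record's sensitivities,
#' flooring at 0 dB. Archetypes: superior/inferior arcuate (Bjerrum-band
#' arc from the blind-spot side to the nasal field), nasal step (nasal
#' locations of one hemifield), paracentral (cluster within ~9 degrees of
#' fixation), advanced (union of arcuate and nasal loss), diffuse
#' cataract-like loss (uniform, so it depresses TD but is largely removed
#' in PD), hemianopia (one side of the vertical midline — a
#' neuro-ophthalmic confounder), myopic rim loss (outer-ring points), and
#' preperimetric (arcuate geometry with depth capped at 1 dB, below the
#' categorization threshold). Sides/hemifields are drawn from the current
#' RNG state where applicable.
#'
#' @param record a `vf_record`.
#' @param archetype one of [vf_archetypes()] other than `"normal"`.
#' @param severity defect depth in dB, >= 0.
#' @param layout a `vf_layout`.
#' @return The modified `vf_record`, relabelled according to the
#'   archetype (glaucoma for glaucomatous archetypes, non-glaucoma for
#'   confounders).
#' @export
apply_archetype <- function(record, archetype, severity,
                            layout = vf_layout()) {
  stopifnot(inherits(record, "vf_record"), severity >= 0)
  if (archetype == "normal") return(record)
  side <- sample(c(-1, 1), 1)
  hemi <- sample(c(-1, 1), 1)
  w <- archetype_mask(archetype, layout, side = side, hemi = hemi)
  depth <- if (archetype == "preperimetric") min(severity, 1) else severity
  s <- pmax(record$sensitivities - depth * w, 0)
  record$sensitivities <- s
  record$archetype <- archetype
  record$label <- if (archetype %in% glaucoma_archetypes()) "glaucoma"
                  else "non_glaucoma"
  record
}

#' Simulate a labelled cohort
#'
#' Draws `n_records` stratified by the class mix, with ages uniform over
#' the configured range and defect severities uniform over the severity
#' range. Records failing the reliability filter are retained but flagged
#' (`reliable` field), so either an exclusion or a keep-all protocol can
#' be replicated downstream. Per-record RNG substreams are derived from
#' the global seed by counter, so the cohort is reproducible record by
#' record.
#'
#' @param config a [sim_config()].
#' @param model a `vf_normative` or [normative_truth()] list.
#' @param layout a `vf_layout`.
#' @return An object of class `vf_cohort`: list with `records` (list of
#'   `vf_record`s carrying `reliable`), and `provenance` (config and
#'   seed).
#' @export
simulate_cohort <- function(config, model = normative_truth(),
                            layout = vf_layout()) {
  stopifnot(inherits(config, "vf_sim_config"))
  set.seed(config$seed)
  classes <- sample(names(config$class_mix), config$n_records,
                    replace = TRUE, prob = config$class_mix)
  substream <- (as.numeric(config$seed) * 48271 +
                  seq_len(max(config$n_records, 1)) * 16807) %% 2147483629
  records <- vector("list", config$n_records)
  for (i in seq_len(config$n_records)) {
    set.seed(substream[i])
    age <- stats::runif(1, config$age_range[1], config$age_range[2])
    eye <- sample(c("right", "left"), 1)
    rec <- sample_normal_field(age, model, id = sprintf("sim%05d", i),
                               eye = eye, noise_sd = config$noise_sd)
    if (classes[i] != "normal") {
      sev <- stats::runif(1, config$severity_range[1],
                          config$severity_range[2])
      rec <- apply_archetype(rec, classes[i], sev, layout)
    }
    rec$reliable <- passes_reliability(rec)$pass
    records[[i]] <- rec
  }
  structure(list(records = records,
                 provenance = list(config = unclass(config),
                                   seed = config$seed)),
            class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  labs <- vapply(x$records, function(r) r$label, character(1))
  cat(sprintf("Simulated cohort: %d records (%d glaucoma, %d non-glaucoma)\n",
              length(x$records), sum(labs == "glaucoma"),
              sum(labs != "glaucoma")))
  invisible(x)
}
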