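#' Write a cohort to CSV
#'
#' One row per record with columns `id, eye, age, fl_num, fl_den, fp, fn,
#' label, archetype, reliable, s01..s52` (sensitivities in the canonical
#' active-location order documented by [write_layout_json()]). The
#' round-trip through [read_cohort_csv()] is lossless.
#'
#' @param records list of `vf_record`s or a `vf_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  if (inherits(records, "vf_cohort")) records <- records$records
  rows <- lapply(records, function(r) {
    s <- as.list(r$sensitivities)
    names(s) <- sprintf("s%02d", 1:52)
    c(list(id = r$id, eye = r$eye, age = r$age, fl_num = r$fl_num,
           fl_den = r$fl_den, fp = r$fp, fn = r$fn, label = r$label,
           archetype = if (is.null(r$archetype)) NA else r$archetype,
           reliable = if (is.null(r$reliable)) NA else r$reliable),
      s)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  # serialize doubles at full precision so the round-trip is bit-exact
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the documented schema; malformed rows are reported with
#' their line numbers and the offending columns.
#'
#' @param path input CSV path.
#' @return List of `vf_record`s.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "eye", "age", "fl_num", "fl_den", "fp", "fn",
                "label", sprintf("s%02d", 1:52))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scols <- sprintf("s%02d", 1:52)
  records <- vector("list", nrow(df))
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      vf_record(
        id = df$id[i], eye = df$eye[i], age = df$age[i],
        sensitivities = as.numeric(df[i, scols]),
        fl_num = df$fl_num[i], fl_den = df$fl_den[i],
        fp = df$fp[i], fn = df$fn[i], label = df$label[i],
        archetype = if ("archetype" %in% names(df)) df$archetype[i]
                    else NA_character_
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(rec)) {
      errors <- c(errors, sprintf("line %d: %s", i + 1L, rec))
    } else {
      if ("reliable" %in% names(df)) rec$reliable <- df$reliable[i]
      records[[i]] <- rec
    }
  }
  if (length(errors)) {
    stop("cohort CSV parse error\n", paste(errors, collapse = "\n"),
         call. = FALSE)
  }
  records
}

#' Data-point bookkeeping
#'
#' The number of analysed data points is the product of reports, maps
#' per report (1 for a PDP-only pipeline, 3 when the ND and NDP maps are
#' also consumed) and the active-location count of the layout (52 for
#' 24-2).
#'
#' @param n_reports number of VF reports, >= 0.
#' @param maps_per_report 1 or 3.
#' @param layout a `vf_layout`.
#' @return List with `n_reports`, `maps_per_report`, `points`.
#' @export
count_data_points <- function(n_reports, maps_per_report = 3,
                              layout = vf_layout()) {
  if (n_reports < 0) stop("`n_reports` must be >= 0", call. = FALSE)
  if (!maps_per_report %in% c(1, 3)) {
    stop("`maps_per_report` must be 1 or 3", call. = FALSE)
  }
  list(n_reports = n_reports, maps_per_report = maps_per_report,
       points = n_reports * maps_per_report * length(layout$active))
}

#' Hash a configuration object for provenance
#'
#' Canonical-JSON MD5 of any serializable configuration, recorded in
#' output artifacts so reruns can be matched to their settings.
#'
#' @param config any jsonlite-serializable object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}
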