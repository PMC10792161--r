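#' Cohort manifests and metric tables
#'
#' A cohort manifest is a tibble with one row per slab image: columns
#' `subject_id`, `eye_label` (`"study"`/`"fellow"`), `slab_kind`, `path`,
#' `scan_width_mm`, `fovea_row_px`, `fovea_col_px`, `ssi`. It is the plumbing
#' that pairs study and fellow eyes of each subject and points at the image
#' files to quantify.
#'
#' @param path CSV file with the columns above.
#' @return A tibble (classed `octa_manifest`).
#' @export
read_cohort_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         subject_id = readr::col_character(),
                         eye_label = readr::col_character(),
                         slab_kind = readr::col_character(),
                         path = readr::col_character(),
                         .default = readr::col_double()
                       ))
  validate_manifest(m)
}

validate_manifest <- function(m) {
  required <- c("subject_id", "eye_label", "slab_kind", "path", "ssi")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0("Manifest is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_eye <- dplyr::filter(m, !.data$eye_label %in% c("study", "fellow"))
  if (nrow(bad_eye) > 0) {
    abort("Manifest `eye_label` must be 'study' or 'fellow'.")
  }
  dup <- m |>
    dplyr::count(.data$subject_id, .data$eye_label, .data$slab_kind) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Each subject may have at most one %s per eye: %d duplicated rows.",
      "slab of a given kind", sum(dup$n)))
  }
  class(m) <- c("octa_manifest", class(m))
  m
}

#' Apply the signal-strength inclusion filter
#'
#' Keeps manifest rows whose signal strength index is *strictly* greater than
#' `ssi_min` (default 8, i.e. the "> 8/10" quality gate). Rows with a missing
#' SSI are never silently dropped: they are excluded and reported.
#'
#' @param manifest A manifest tibble with an `ssi` column (see
#'   [read_cohort_manifest()]).
#' @param ssi_min Inclusion threshold; rows must satisfy `ssi > ssi_min`.
#' @param quiet Suppress the exclusion message.
#' @return The filtered manifest. Attributes `n_excluded` and `n_missing_ssi`
#'   record what was removed.
#' @export
apply_inclusion_filter <- function(manifest, ssi_min = 8, quiet = FALSE) {
  if (!"ssi" %in% names(manifest)) abort("Manifest has no `ssi` column.")
  missing_ssi <- is.na(manifest$ssi)
  keep <- !missing_ssi & manifest$ssi > ssi_min
  out <- manifest[keep, , drop = FALSE]
  n_excl <- sum(!keep)
  if (!quiet && (n_excl > 0 || any(missing_ssi))) {
    inform(sprintf(
      "Inclusion filter (SSI > %g): kept %d of %d rows; excluded %d (%d with missing SSI).",
      ssi_min, nrow(out), nrow(manifest), n_excl, sum(missing_ssi)))
  }
  attr(out, "n_excluded") <- n_excl
  attr(out, "n_missing_ssi") <- sum(missing_ssi)
  out
}

# Canonical metric column order shared by the writers, readers and the
# cohort generator/summary. The names mirror the standard report layout.
cohort_metric_names <- function() {
  c("scp_pd", "scp_vld", "scp_vdi",
    "dcp_pd", "dcp_vld", "dcp_vdi",
    "pdcc", "ez_norm")
}

metric_labels <- function() {
  c(scp_pd  = "SCP perfusion density (%)",
    scp_vld = "SCP vessel length density (%)",
    scp_vdi = "SCP vessel diameter index",
    dcp_pd  = "DCP perfusion density (%)",
    dcp_vld = "DCP vessel length density (%)",
    dcp_vdi = "DCP vessel diameter index",
    pdcc    = "CC perfusion density (%)",
    ez_norm = "EZ normalized reflectivity")
}

#' Write / read a per-eye metric table
#'
#' The cohort table has one row per eye: `subject_id`, `eye` and one column
#' per metric (`scp_pd`, `scp_vld`, `scp_vdi`, `dcp_pd`, `dcp_vld`,
#' `dcp_vdi`, `pdcc`, `ez_norm`). Values round-trip losslessly through the
#' CSV (shortest round-trip decimal representation); missing measurements
#' are empty cells restored as `NA`.
#'
#' @param records A data frame with columns `subject_id`, `eye` and at least
#'   one metric column; all rows share one schema.
#' @param path Output CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_cohort_table <- function(records, path) {
  records <- as_tibble(records)
  required <- c("subject_id", "eye")
  if (!all(required %in% names(records))) {
    abort("Cohort records need `subject_id` and `eye` columns.")
  }
  metric_cols <- setdiff(names(records), required)
  if (nrow(records) > 0) {
    bad <- !vapply(records[metric_cols], is.numeric, logical(1))
    if (any(bad)) {
      abort(paste0("Non-numeric metric columns: ",
                   paste(metric_cols[bad], collapse = ", ")))
    }
    if (!all(records$eye %in% c("study", "fellow"))) {
      abort("`eye` must be 'study' or 'fellow'.")
    }
  }
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    eye = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
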