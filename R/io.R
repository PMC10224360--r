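#' Read an EPG recording from CSV + JSON sidecar
#'
#' The CSV must have the header `time_s,voltage_uv`; the metadata sidecar is
#' `<stem>.meta.json` next to the CSV and holds `fs`, `plant_id`, `treatment`
#' and `phase`. Timing authority is `fs` from the sidecar: the time column is
#' cross-checked against it (median time step; relative mismatch above 1% is
#' an error) and otherwise discarded, which avoids floating-point accumulation
#' drift. Each failure mode raises a distinct condition class:
#' `electrome_error_missing_sidecar`, `electrome_error_nonfinite_values`,
#' `electrome_error_nonmonotone_time`, `electrome_error_fs_mismatch`.
#'
#' @param path Path to the recording CSV.
#' @return An [epg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop_electrome(sprintf("recording file not found: %s", path), "missing_file")
  }
  meta_path <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (!file.exists(meta_path)) {
    stop_electrome(sprintf("metadata sidecar not found: %s", meta_path),
                   "missing_sidecar")
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  for (field in c("fs", "plant_id", "treatment", "phase")) {
    if (is.null(meta[[field]])) {
      stop_electrome(sprintf("sidecar %s lacks field `%s`", meta_path, field),
                     "bad_sidecar")
    }
  }
  # base read.csv: strtod parsing is correctly rounded, so 17-significant-digit
  # voltages round-trip bit-identically
  dat <- utils::read.csv(path, colClasses = c("numeric", "numeric"))
  if (!identical(names(dat), c("time_s", "voltage_uv"))) {
    stop_electrome(sprintf("%s must have header time_s,voltage_uv", path),
                   "bad_header")
  }
  if (any(!is.finite(dat$voltage_uv)) || any(!is.finite(dat$time_s))) {
    stop_electrome(sprintf("%s contains non-finite values", path),
                   "nonfinite_values")
  }
  if (nrow(dat) >= 2L) {
    dt <- diff(dat$time_s)
    if (any(dt <= 0)) {
      stop_electrome(sprintf("%s has a non-monotone time column", path),
                     "nonmonotone_time")
    }
    fs_obs <- 1 / median(dt)
    if (abs(fs_obs - meta$fs) / meta$fs > 0.01) {
      stop_electrome(sprintf(
        "%s: sampling rate mismatch (sidecar fs = %g Hz, time column implies %g Hz)",
        path, meta$fs, fs_obs), "fs_mismatch")
    }
  }
  epg_recording(dat$voltage_uv, fs = meta$fs, plant_id = meta$plant_id,
                treatment = meta$treatment, phase = meta$phase)
}

#' Write an EPG recording to CSV + JSON sidecar
#'
#' Voltages are serialized with 17 significant digits so the file round-trips
#' bit-identically through [read_recording()]. The time column is written for
#' human inspection only (`time_s = i / fs`).
#'
#' @param recording An [epg_recording()].
#' @param path Destination CSV path; the sidecar `<stem>.meta.json` is written
#'   alongside it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!is_recording(recording)) {
    stop_electrome("`recording` must be an epg_recording", "bad_recording")
  }
  n <- length(recording$samples)
  lines <- c("time_s,voltage_uv",
             sprintf("%.6f,%.17g", (seq_len(n) - 1) / recording$fs,
                     recording$samples))
  writeLines(lines, path)
  meta_path <- paste0(sub("\\.csv$", "", path), ".meta.json")
  jsonlite::write_json(
    list(fs = recording$fs, plant_id = recording$plant_id,
         treatment = recording$treatment, phase = recording$phase,
         units = "uV", n_samples = n),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Write a cohort of recordings plus a manifest
#'
#' Writes one CSV (+ sidecar) per recording under `dir` and a cohort manifest
#' JSON listing the relative file paths with their labels.
#'
#' @param cohort A cohort tibble as returned by [generate_cohort()] (columns
#'   `plant_id`, `treatment`, `phase`, `fs`, `recording`).
#' @param dir Output directory (created if missing).
#' @param manifest_name File name of the manifest JSON inside `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest_name = "cohort_manifest.json") {
  cohort <- as_cohort(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("%s_%s_%s.csv", cohort$treatment, cohort$plant_id, cohort$phase)
  for (i in seq_len(nrow(cohort))) {
    write_recording(cohort$recording[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    fs = unique(cohort$fs),
    recordings = lapply(seq_len(nrow(cohort)), function(i) {
      list(path = files[i], plant_id = cohort$plant_id[i],
           treatment = cohort$treatment[i], phase = cohort$phase[i])
    })
  )
  manifest_path <- file.path(dir, manifest_name)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort manifest back into a cohort tibble
#'
#' @param manifest_path Path to a cohort manifest JSON written by
#'   [write_cohort()]; recording paths are resolved relative to it.
#' @return A cohort tibble (see [generate_cohort()]).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_electrome(sprintf("cohort manifest not found: %s", manifest_path),
                   "missing_file")
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  entries <- manifest$recordings
  if (length(entries) == 0L) {
    stop_electrome("cohort manifest lists no recordings", "empty_manifest")
  }
  base <- dirname(manifest_path)
  recs <- map(entries, function(e) read_recording(file.path(base, e$path)))
  fs <- unique(map_dbl(recs, "fs"))
  if (length(fs) != 1L) {
    stop_electrome("recordings in a cohort must share the sampling rate",
                   "mixed_fs")
  }
  tibble(
    plant_id = map_chr_local(recs, "plant_id"),
    treatment = map_chr_local(recs, "treatment"),
    phase = map_chr_local(recs, "phase"),
    fs = fs,
    recording = recs
  )
}

# Normalise cohort inputs: accept the cohort tibble or a bare list of
# recordings. Recordings within a (treatment, phase) group must share length,
# and all must share fs.
as_cohort <- function(cohort) {
  if (is.data.frame(cohort) && "recording" %in% names(cohort)) {
    recs <- cohort$recording
  } else if (is.list(cohort) && all(vapply(cohort, is_recording, logical(1)))) {
    recs <- cohort
  } else {
    stop_electrome("`cohort` must be a cohort tibble or a list of epg_recording",
                   "bad_cohort")
  }
  if (length(recs) == 0L) stop_electrome("cohort is empty", "bad_cohort")
  fs <- unique(map_dbl(recs, "fs"))
  if (length(fs) != 1L) {
    stop_electrome("recordings in a cohort must share the sampling rate",
                   "mixed_fs")
  }
  out <- tibble(
    plant_id = map_chr_local(recs, "plant_id"),
    treatment = map_chr_local(recs, "treatment"),
    phase = map_chr_local(recs, "phase"),
    fs = fs,
    recording = recs
  )
  lens <- tibble(treatment = out$treatment, phase = out$phase,
                 len = vapply(recs, function(r) length(r$samples), numeric(1)))
  bad <- lens |>
    group_by(.data$treatment, .data$phase) |>
    summarise(k = dplyr::n_distinct(.data$len), .groups = "drop") |>
    filter(.data$k > 1L)
  if (nrow(bad) > 0L) {
    stop_electrome(sprintf(
      "recordings in group (%s, %s) differ in length",
      bad$treatment[1], bad$phase[1]), "mismatched_lengths")
  }
  out
}
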