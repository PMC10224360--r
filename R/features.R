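#' Per-minute feature extraction for a replicate cohort
#'
#' Computes, for every recording and every full analysis window (default one
#' minute): the mean frequency (spectral centroid of the detrended window),
#' the mean DDP (raw window mean, uV), and the average band power of each
#' band (Welch PSD of the detrended window integrated by composite Simpson).
#'
#' @param cohort A cohort tibble ([generate_cohort()], [read_cohort()]) or a
#'   list of [epg_recording()] objects.
#' @param bands Band definition table (default [default_bands()]).
#' @param seg_seconds Analysis window length in seconds (default 60).
#' @param window_seconds,overlap_fraction,taper Welch parameters, see
#'   [welch_psd()].
#' @param mean_frequency_mode Weighting of the mean frequency, see
#'   [mean_frequency()].
#' @return A tidy tibble with columns `plant_id`, `treatment`, `phase`,
#'   `minute`, `feature`, `value`, `units`. Features are `mean_frequency`
#'   (Hz), `mean_ddp` (uV) and `abp:<band>` (uV^2).
#' @examples
#' cfg <- generator_config(duration_s = 180, n_replicates = 2, base_seed = 7)
#' feats <- epg_features(generate_cohort(cfg))
#' dplyr::count(feats, feature)
#' @export
epg_features <- function(cohort, bands = default_bands(), seg_seconds = 60,
                         window_seconds = 4, overlap_fraction = 0.5,
                         taper = "hann",
                         mean_frequency_mode = c("centroid", "magnitude_mean")) {
  mean_frequency_mode <- match.arg(mean_frequency_mode)
  cohort <- as_cohort(cohort)
  fs <- cohort$fs[1]
  bands <- clip_bands(bands, fs / 2)  # warn once, not once per minute
  per_recording <- map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$recording[[i]]
    wins <- segment_minutes(rec, seg_seconds)
    rows <- imap(wins, function(w, k) {
      psd <- welch_psd(w - mean(w), fs, window_seconds, overlap_fraction, taper)
      bp <- vapply(seq_len(nrow(bands)), function(j) {
        band_power(psd, bands[j, ], warn = FALSE)
      }, numeric(1))
      tibble(
        minute = k - 1L,
        feature = c("mean_frequency", "mean_ddp", paste0("abp:", bands$name)),
        value = c(mean_frequency(w, fs, mean_frequency_mode), mean_ddp(w), bp),
        units = c("Hz", "uV", rep("uV^2", nrow(bands)))
      )
    })
    out <- list_rbind(rows)
    out$plant_id <- cohort$plant_id[i]
    out$treatment <- cohort$treatment[i]
    out$phase <- cohort$phase[i]
    out
  })
  out <- list_rbind(per_recording)
  out <- out[, c("plant_id", "treatment", "phase", "minute", "feature",
                 "value", "units")]
  arrange(out, .data$treatment, .data$phase, .data$feature, .data$minute,
          .data$plant_id)
}
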