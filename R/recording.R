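#' Construct an EPG recording
#'
#' A recording is one replicate's micro-voltage time series: the difference of
#' electrical potential between two electrodes (DDP, in uV) sampled uniformly
#' at `fs` Hz, together with its plant, treatment and phase labels.
#'
#' @param samples Numeric vector of voltages in uV; all values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param plant_id Replicate label.
#' @param treatment Treatment label (e.g. the host species presented).
#' @param phase Phase label: `"before"` or `"after"` stimulus presentation.
#' @return An object of class `epg_recording`.
#' @examples
#' rec <- epg_recording(sin(2 * pi * (0:6249) / 62.5), fs = 62.5)
#' rec
#' @export
epg_recording <- function(samples, fs, plant_id = "plant01",
                          treatment = "synthetic", phase = "before") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_electrome("`samples` must be a non-empty numeric vector", "bad_recording")
  }
  if (any(!is.finite(samples))) {
    stop_electrome("recording contains non-finite voltage values",
                   "nonfinite_values")
  }
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         plant_id = as.character(plant_id), treatment = as.character(treatment),
         phase = as.character(phase)),
    class = "epg_recording"
  )
}

#' @export
print.epg_recording <- function(x, ...) {
  cat(sprintf(
    "<epg_recording> %s / %s / %s: %d samples at %g Hz (%.1f s), rms %.2f uV\n",
    x$plant_id, x$treatment, x$phase, length(x$samples), x$fs,
    length(x$samples) / x$fs, sqrt(mean((x$samples - mean(x$samples))^2))
  ))
  invisible(x)
}

#' @method as_tibble epg_recording
#' @export
as_tibble.epg_recording <- function(x, ...) {
  tibble(time_s = (seq_along(x$samples) - 1) / x$fs, voltage_uv = x$samples)
}

#' @method tidy epg_recording
#' @export
tidy.epg_recording <- function(x, ...) as_tibble(x)

is_recording <- function(x) inherits(x, "epg_recording")

# length of a recording in full analysis minutes
n_full_minutes <- function(rec, seg_seconds = 60) {
  floor(length(rec$samples) / round(seg_seconds * rec$fs))
}
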