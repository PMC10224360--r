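#' Split a recording into consecutive analysis windows
#'
#' Returns consecutive, non-overlapping windows of `round(seg_seconds * fs)`
#' samples; a trailing partial window is dropped. All figures downstream are
#' minute-by-minute, so the default window is 60 s.
#'
#' @param recording An [epg_recording()], or a numeric vector (then `fs` must
#'   be given).
#' @param seg_seconds Window length in seconds; `seg_seconds * fs` must be at
#'   least 2 samples.
#' @param fs Sampling rate, required when `recording` is a bare vector.
#' @return A list of numeric windows, in temporal order.
#' @export
segment_minutes <- function(recording, seg_seconds = 60, fs = NULL) {
  if (is_recording(recording)) {
    x <- recording$samples
    fs <- recording$fs
  } else {
    x <- recording
    if (is.null(fs)) stop_electrome("`fs` is required for a bare sample vector",
                                    "config")
  }
  win <- round(seg_seconds * fs)
  if (win < 2) {
    stop_electrome("`seg_seconds * fs` must be at least 2 samples", "config")
  }
  nwin <- floor(length(x) / win)
  if (nwin < 1L) {
    stop_electrome(sprintf(
      "recording of %d samples is shorter than one %g s window (%d samples)",
      length(x), seg_seconds, win), "too_short", validation = FALSE)
  }
  lapply(seq_len(nwin), function(i) x[((i - 1) * win + 1):(i * win)])
}

# one-sided power spectrum of a window via the real FFT:
# returns freqs (0..fs/2) and squared magnitudes |X(f)|^2
rfft_power <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  nhalf <- floor(n / 2) + 1L
  list(freqs = (seq_len(nhalf) - 1) * fs / n,
       power = Mod(X[seq_len(nhalf)])^2,
       magnitude = Mod(X[seq_len(nhalf)]))
}

#' Per-window mean frequency (spectral centroid)
#'
#' The "mean of the frequencies" of a window: the window is detrended by
#' subtracting its mean, transformed with the real FFT, and the mean frequency
#' is the weighted average of the positive frequencies. `mode = "centroid"`
#' (default) weights by spectral power `|X(f)|^2` -- the standard spectral
#' centroid; `mode = "magnitude_mean"` weights by `|X(f)|` instead.
#'
#' @param window Numeric sample window.
#' @param fs Sampling rate in Hz.
#' @param mode Weighting: `"centroid"` (power) or `"magnitude_mean"`.
#' @return Mean frequency in Hz, in `[0, fs/2]`.
#' @export
mean_frequency <- function(window, fs, mode = c("centroid", "magnitude_mean")) {
  mode <- match.arg(mode)
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  x <- window - mean(window)
  if (all(x == 0)) {
    stop_electrome("mean frequency is undefined for an all-constant window",
                   "undefined_centroid", validation = FALSE)
  }
  sp <- rfft_power(x, fs)
  pos <- -1L  # drop the DC bin
  w <- if (mode == "centroid") sp$power[pos] else sp$magnitude[pos]
  sum(sp$freqs[pos] * w) / sum(w)
}

#' Per-window mean potential difference (DDP)
#'
#' Arithmetic mean of the raw (not detrended) window, in uV.
#'
#' @param window Numeric sample window (non-empty).
#' @return Mean DDP in uV.
#' @export
mean_ddp <- function(window) {
  if (length(window) == 0L) stop_electrome("empty window", "bad_window")
  mean(window)
}

#' Welch power spectral density estimate
#'
#' Splits the input into overlapping tapered segments, removes each segment's
#' mean, computes a one-sided periodogram per segment and averages them. With
#' the defaults (4 s Hann segments, 50% overlap) the frequency grid runs from
#' 0 to `fs/2` in steps of `1/window_seconds` Hz and the density is scaled so
#' that its integral over `[0, fs/2]` approximates the signal variance
#' (one-sided density, taper-power corrected).
#'
#' @param samples Numeric vector, at least `window_seconds * fs` samples.
#' @param fs Sampling rate in Hz.
#' @param window_seconds Segment length in seconds (default 4).
#' @param overlap_fraction Fractional overlap between consecutive segments
#'   (default 0.5).
#' @param taper Segment taper: `"hann"` (default) or `"boxcar"`.
#' @return An `epg_psd` object with fields `freqs_hz`, `density` (uV^2/Hz),
#'   and the estimation parameters; see [tidy.epg_psd()].
#' @examples
#' x <- rnorm(62.5 * 60)
#' psd <- welch_psd(x, fs = 62.5)
#' glance(psd)
#' @export
welch_psd <- function(samples, fs, window_seconds = 4, overlap_fraction = 0.5,
                      taper = c("hann", "boxcar")) {
  taper <- match.arg(taper)
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  check_number(window_seconds, "window_seconds", lower = 0, allow_equal_lower = FALSE)
  check_number(overlap_fraction, "overlap_fraction", lower = 0, upper = 1,
               allow_equal_upper = FALSE)
  nperseg <- round(window_seconds * fs)
  n <- length(samples)
  if (n < nperseg) {
    stop_electrome(sprintf(
      "input of %d samples is shorter than one %g s segment (%d samples)",
      n, window_seconds, nperseg), "too_short", validation = FALSE)
  }
  step <- nperseg - floor(nperseg * overlap_fraction)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)  # periodic Hann
  } else {
    rep(1, nperseg)
  }
  idx <- outer(0:(nperseg - 1L), starts, `+`)
  seg <- matrix(samples[idx], nrow = nperseg)
  seg <- sweep(seg, 2L, colMeans(seg))  # per-segment constant detrend
  seg <- seg * w
  X <- mvfft(seg)
  nf <- nperseg %/% 2L + 1L
  p <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (fs * sum(w^2))
  # one-sided doubling; DC never doubled, Nyquist only present for even nperseg
  dbl <- if (nperseg %% 2L == 0L) seq(2L, nf - 1L) else seq(2L, nf)
  p[dbl, ] <- 2 * p[dbl, ]
  structure(
    list(freqs_hz = (seq_len(nf) - 1) * fs / nperseg,
         density = rowMeans(p),
         fs = fs, window_seconds = window_seconds,
         overlap_fraction = overlap_fraction, taper_name = taper,
         n_segments = length(starts)),
    class = "epg_psd"
  )
}

#' Construct a PSD estimate from explicit grid values
#'
#' Mostly useful for testing band integration against analytically integrable
#' densities.
#'
#' @param freqs_hz Ascending, equally spaced frequency grid starting at 0.
#' @param density Non-negative density values, same length as `freqs_hz`.
#' @param fs Sampling rate implied by the grid (default `2 * max(freqs_hz)`).
#' @return An `epg_psd` object.
#' @export
psd_estimate <- function(freqs_hz, density, fs = 2 * max(freqs_hz)) {
  if (length(freqs_hz) != length(density)) {
    stop_electrome("`freqs_hz` and `density` must have equal length", "bad_psd")
  }
  if (any(density < 0)) stop_electrome("`density` must be non-negative", "bad_psd")
  if (length(freqs_hz) >= 2L) {
    d <- diff(freqs_hz)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * d[1]) {
      stop_electrome("`freqs_hz` must be ascending and equally spaced", "bad_psd")
    }
  }
  structure(
    list(freqs_hz = freqs_hz, density = density, fs = fs,
         window_seconds = if (length(freqs_hz) >= 2L) 1 / diff(freqs_hz)[1] else NA_real_,
         overlap_fraction = NA_real_, taper_name = "none", n_segments = 1L),
    class = "epg_psd"
  )
}

#' @export
print.epg_psd <- function(x, ...) {
  cat(sprintf(
    "<epg_psd> %d frequencies 0..%g Hz (df = %g Hz), %d x %g s %s segments\n",
    length(x$freqs_hz), max(x$freqs_hz),
    if (length(x$freqs_hz) >= 2) diff(x$freqs_hz)[1] else NA,
    x$n_segments, x$window_seconds, x$taper_name))
  invisible(x)
}

#' Tidy a PSD estimate
#' @param x An `epg_psd`.
#' @param ... Unused.
#' @return A tibble with columns `freq_hz` and `density_uv2_hz`.
#' @method tidy epg_psd
#' @export
tidy.epg_psd <- function(x, ...) {
  tibble(freq_hz = x$freqs_hz, density_uv2_hz = x$density)
}

#' One-row summary of a PSD estimate
#' @param x An `epg_psd`.
#' @param ... Unused.
#' @return A one-row tibble: grid parameters and total power (rectangle-rule
#'   integral of the density over the full grid, in uV^2).
#' @method glance epg_psd
#' @export
glance.epg_psd <- function(x, ...) {
  df <- if (length(x$freqs_hz) >= 2) diff(x$freqs_hz)[1] else NA_real_
  tibble(
    n_freqs = length(x$freqs_hz), delta_f_hz = df,
    f_max_hz = max(x$freqs_hz), window_seconds = x$window_seconds,
    overlap_fraction = x$overlap_fraction, taper = x$taper_name,
    n_segments = x$n_segments,
    total_power_uv2 = sum(x$density) * df
  )
}

#' @method autoplot epg_psd
#' @export
autoplot.epg_psd <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[dat$freq_hz > 0 & dat$density_uv2_hz > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freq_hz, y = .data$density_uv2_hz)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)))
}

# Composite Simpson integration on a uniform grid. For an even number of
# intervals the standard 1,4,2,...,4,1 weights apply; for an odd number the
# first interval is handled by the trapezoid rule and Simpson covers the rest
# (exact for linear densities either way).
simpson_uniform <- function(x, y) {
  n <- length(x)
  h <- (x[n] - x[1]) / (n - 1)
  if (n == 2L) return((y[1] + y[2]) * h / 2)
  acc <- 0
  i0 <- 1L
  if ((n - 1L) %% 2L == 1L) {  # odd interval count: trapezoid on the first
    acc <- (y[1] + y[2]) * h / 2
    i0 <- 2L
  }
  k <- n - i0 + 1L  # points in the Simpson part (odd, >= 3)
  ws <- rep(1, k)
  ws[seq(2L, k - 1L, by = 2L)] <- 4
  if (k >= 5L) ws[seq(3L, k - 2L, by = 2L)] <- 2
  acc + h / 3 * sum(ws * y[i0:n])
}

#' Average band power: integrate a PSD over a frequency band
#'
#' Integrates the density over the grid points with
#' `f_lo <= f <= min(f_hi, fs/2)`, inclusive at both edges, using the
#' composite Simpson rule. A band reaching above the Nyquist frequency is
#' clipped with a warning (`electrome_warning_nyquist_clip`); with fewer than
#' three in-band grid points the integral falls back to the trapezoid rule
#' (`electrome_warning_trapezoid_fallback`). A band lying entirely above the
#' Nyquist frequency is an error naming the band.
#'
#' @param psd An `epg_psd` from [welch_psd()] or [psd_estimate()].
#' @param band A single band: one row of a bands table or a named list with
#'   `name`, `f_lo_hz`, `f_hi_hz`.
#' @param warn Set `FALSE` to suppress the clipping/fallback warnings (used
#'   internally when the condition has already been reported once).
#' @return Band power in uV^2.
#' @examples
#' psd <- welch_psd(10 * cos(2 * pi * 1 * (0:7499) / 62.5), fs = 62.5)
#' band_power(psd, list(name = "delta", f_lo_hz = 0.5, f_hi_hz = 4))
#' @export
band_power <- function(psd, band, warn = TRUE) {
  if (!inherits(psd, "epg_psd")) {
    stop_electrome("`psd` must be an epg_psd", "bad_psd")
  }
  band <- as_band(band)
  f <- psd$freqs_hz
  nyquist <- max(f)
  eps <- 1e-9 * max(nyquist, 1)
  if (band$f_lo_hz > nyquist + eps) {
    stop_electrome(sprintf(
      "band `%s` (%g-%g Hz) lies entirely above the Nyquist frequency %g Hz",
      band$name, band$f_lo_hz, band$f_hi_hz, nyquist),
      "empty_band", validation = FALSE)
  }
  hi <- band$f_hi_hz
  if (hi > nyquist + eps) {
    if (warn) {
      warn_electrome(sprintf(
        "band `%s` clipped at the Nyquist frequency: integrating over [%g, %g] Hz",
        band$name, band$f_lo_hz, nyquist), "nyquist_clip")
    }
    hi <- nyquist
  }
  idx <- which(f >= band$f_lo_hz - eps & f <= hi + eps)
  if (length(idx) == 0L) {
    stop_electrome(sprintf("band `%s` contains no PSD grid points", band$name),
                   "empty_band", validation = FALSE)
  }
  if (length(idx) == 1L) return(0)
  if (length(idx) < 3L) {
    if (warn) {
      warn_electrome(sprintf(
        "band `%s` spans fewer than 3 grid points; using the trapezoid rule",
        band$name), "trapezoid_fallback")
    }
    h <- f[idx[2]] - f[idx[1]]
    return((psd$density[idx[1]] + psd$density[idx[2]]) * h / 2)
  }
  simpson_uniform(f[idx], psd$density[idx])
}

# Clip bands to the Nyquist frequency once, warning per band, so per-minute
# loops do not repeat the warning 120 times.
clip_bands <- function(bands, nyquist) {
  bands <- validate_bands(bands)
  drop <- bands$f_lo_hz > nyquist
  if (any(drop)) {
    stop_electrome(sprintf(
      "band `%s` (%g-%g Hz) lies entirely above the Nyquist frequency %g Hz",
      bands$name[which(drop)[1]], bands$f_lo_hz[which(drop)[1]],
      bands$f_hi_hz[which(drop)[1]], nyquist), "empty_band", validation = FALSE)
  }
  clip <- bands$f_hi_hz > nyquist
  if (any(clip)) {
    for (nm in bands$name[clip]) {
      warn_electrome(sprintf(
        "band `%s` clipped at the Nyquist frequency %g Hz", nm, nyquist),
        "nyquist_clip")
    }
    bands$f_hi_hz[clip] <- nyquist
  }
  bands
}

#' Per-minute average band power series for one recording
#'
#' For each full analysis window (default one minute): subtract the window
#' mean, estimate the Welch PSD, and integrate it over each band. Output rows
#' are indexed identically across bands by the 0-based `minute` index.
#'
#' @param recording An [epg_recording()].
#' @param bands Band definition table (default [default_bands()]).
#' @param seg_seconds Analysis window length in seconds (default 60).
#' @param window_seconds,overlap_fraction,taper Passed to [welch_psd()].
#' @return A tibble with columns `feature` (`"abp:<band>"`), `minute`,
#'   `value`, `units` (`"uV^2"`).
#' @export
abp_series <- function(recording, bands = default_bands(), seg_seconds = 60,
                       window_seconds = 4, overlap_fraction = 0.5,
                       taper = "hann") {
  if (!is_recording(recording)) {
    stop_electrome("`recording` must be an epg_recording", "bad_recording")
  }
  bands <- clip_bands(bands, recording$fs / 2)
  wins <- segment_minutes(recording, seg_seconds)
  rows <- imap(wins, function(w, i) {
    psd <- welch_psd(w - mean(w), recording$fs, window_seconds,
                     overlap_fraction, taper)
    tibble(
      feature = paste0("abp:", bands$name),
      minute = i - 1L,
      value = vapply(seq_len(nrow(bands)), function(j) {
        band_power(psd, bands[j, ], warn = FALSE)
      }, numeric(1)),
      units = "uV^2"
    )
  })
  arrange(list_rbind(rows), .data$feature, .data$minute)
}
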