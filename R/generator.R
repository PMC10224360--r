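#' Oscillatory component of the synthetic electrome
#'
#' A band-limited stochastic oscillation: Gaussian noise restricted to the
#' frequency interval `center_hz +/- bandwidth_hz / 2` and calibrated to a
#' target root-mean-square amplitude. `bandwidth_hz = 0` degenerates to a pure
#' sinusoid at `center_hz` with uniformly random phase and amplitude
#' `rms_uv * sqrt(2)`. Amplitudes are calibrated by rms, not peak, because
#' field reports quote amplitude ranges rather than waveforms.
#'
#' @param center_hz Centre frequency in Hz (must not exceed the Nyquist
#'   frequency of the configuration it is used in).
#' @param bandwidth_hz Full bandwidth in Hz (>= 0).
#' @param rms_uv Target rms amplitude in uV (>= 0).
#' @return An `epg_component` record.
#' @export
oscillatory_component <- function(center_hz, bandwidth_hz = 0, rms_uv = 10) {
  check_number(center_hz, "center_hz", lower = 0)
  check_number(bandwidth_hz, "bandwidth_hz", lower = 0)
  check_number(rms_uv, "rms_uv", lower = 0)
  structure(list(center_hz = center_hz, bandwidth_hz = bandwidth_hz,
                 rms_uv = rms_uv), class = "epg_component")
}

#' Default oscillatory components of the synthetic electrome
#'
#' Two band-limited components emulating electrome energy concentrated at low
#' frequencies: a dominant 0--0.5 Hz component (60 uV rms) and a weaker
#' delta-range component spanning 0.5--3.5 Hz (15 uV rms). Together with the
#' default 20 uV rms 1/f background the total signal rms is ~65 uV, with
#' excursions inside the 5--250 uV amplitude range typical of plant surface
#' potentials.
#'
#' @return A list of [oscillatory_component()] records.
#' @export
default_components <- function() {
  list(
    oscillatory_component(center_hz = 0.25, bandwidth_hz = 0.5, rms_uv = 60),
    oscillatory_component(center_hz = 2,    bandwidth_hz = 3,   rms_uv = 15)
  )
}

#' Step modulation of band-limited components
#'
#' Models a sustained change in the energy of one or more frequency bands
#' starting at a fixed time after a stimulus ("host presentation"): from
#' `onset_s` seconds into the after phase, every component whose centre
#' frequency lies inside a named band has its amplitude multiplied by
#' `sqrt(gain)`, i.e. its power by `gain`. The default emulates a sustained
#' three-fold rise of low-band (0--0.5 Hz) power beginning 20 min in.
#'
#' @param onset_s Onset time in seconds from the start of the after phase.
#' @param band_gains Named numeric vector mapping band name to a
#'   multiplicative power gain (finite, >= 0).
#' @param bands Band definition table used to resolve the names.
#' @return An `epg_modulation` record.
#' @export
step_modulation <- function(onset_s = 1200, band_gains = c(low = 3),
                            bands = default_bands()) {
  check_number(onset_s, "onset_s", lower = 0)
  if (!is.numeric(band_gains) || is.null(names(band_gains)) ||
      any(!nzchar(names(band_gains)))) {
    stop_electrome("invalid value for field `band_gains`: must be a named numeric vector",
                   "config")
  }
  if (any(!is.finite(band_gains)) || any(band_gains < 0)) {
    stop_electrome("invalid value for field `band_gains`: gains must be finite and >= 0",
                   "config")
  }
  bands <- validate_bands(bands)
  missing <- setdiff(names(band_gains), bands$name)
  if (length(missing) > 0L) {
    stop_electrome(sprintf("invalid value for field `band_gains`: unknown band `%s`",
                           missing[1]), "config")
  }
  resolved <- bands[match(names(band_gains), bands$name), ]
  resolved$gain <- unname(band_gains)
  structure(list(onset_s = onset_s, band_gains = resolved),
            class = "epg_modulation")
}

#' Synthetic electrome generator configuration
#'
#' Defines the study conditions a generated cohort emulates: 2 h (7200 s)
#' phases sampled at 62.5 Hz (450,000 points per phase), 23 replicate plants
#' per treatment, a 1/f^beta coloured-noise background and band-limited
#' oscillatory components, optionally step-modulated in the after phase.
#'
#' @param fs Sampling rate in Hz (default 62.5).
#' @param duration_s Phase length in seconds (default 7200).
#' @param n_replicates Number of replicate plants (default 23).
#' @param background_exponent Exponent beta of the 1/f^beta background power
#'   law (default 1, i.e. pink noise; 0 gives white noise).
#' @param background_rms Background rms amplitude in uV (default 20).
#' @param components List of [oscillatory_component()] records.
#' @param modulation Optional [step_modulation()] applied in the after phase.
#' @param base_seed Integer seed from which per-recording seeds are derived.
#' @return An `epg_generator_config` record.
#' @examples
#' cfg <- generator_config(duration_s = 120, n_replicates = 2, base_seed = 1)
#' generate_recording(cfg, replicate_index = 0, phase = "before")
#' @export
generator_config <- function(fs = 62.5, duration_s = 7200, n_replicates = 23,
                             background_exponent = 1, background_rms = 20,
                             components = default_components(),
                             modulation = NULL, base_seed = 1L) {
  check_number(fs, "fs", lower = 0, allow_equal_lower = FALSE)
  check_number(duration_s, "duration_s", lower = 0, allow_equal_lower = FALSE)
  check_number(n_replicates, "n_replicates", lower = 1)
  if (n_replicates != round(n_replicates)) {
    stop_electrome("invalid value for field `n_replicates`: must be an integer",
                   "config")
  }
  check_number(background_exponent, "background_exponent", lower = 0)
  check_number(background_rms, "background_rms", lower = 0)
  check_number(base_seed, "base_seed")
  if (!is.list(components) ||
      !all(vapply(components, inherits, logical(1), "epg_component"))) {
    stop_electrome("invalid value for field `components`: must be a list of oscillatory_component()",
                   "config")
  }
  for (comp in components) {
    if (comp$center_hz > fs / 2) {
      stop_electrome(sprintf(
        "invalid value for field `center_hz`: component at %g Hz exceeds the Nyquist frequency %g Hz",
        comp$center_hz, fs / 2), "config")
    }
  }
  if (!is.null(modulation)) {
    if (!inherits(modulation, "epg_modulation")) {
      stop_electrome("invalid value for field `modulation`: must be a step_modulation()",
                     "config")
    }
    if (modulation$onset_s > duration_s) {
      stop_electrome("invalid value for field `onset_s`: onset_s exceeds duration_s",
                     "config")
    }
  }
  structure(
    list(fs = fs, duration_s = duration_s, n_replicates = as.integer(n_replicates),
         background_exponent = background_exponent, background_rms = background_rms,
         components = components, modulation = modulation,
         base_seed = as.integer(base_seed)),
    class = "epg_generator_config"
  )
}

# Seed derivation: documented so fixtures are stable across sessions.
# before phase offset 0, after phase offset 1; stride 10007 between replicates.
recording_seed <- function(config, replicate_index, phase) {
  config$base_seed + 10007L * as.integer(replicate_index) +
    if (identical(phase, "after")) 1L else 0L
}

# 1/f^beta background: shape the rFFT of white Gaussian noise by f^(-beta/2),
# zero the DC term, invert, and rescale to the target rms.
shaped_background <- function(n, fs, beta, rms) {
  if (rms == 0) return(numeric(n))
  x <- rnorm(n)
  if (beta == 0) return(x * rms / sqrt(mean(x^2)))
  X <- fft(x)
  nhalf <- floor(n / 2) + 1L
  k <- 2:nhalf
  f <- (k - 1) * fs / n
  X[1] <- 0 + 0i
  X[k] <- X[k] * f^(-beta / 2)
  if (n %% 2 == 0) X[nhalf] <- complex(real = Re(X[nhalf]), imaginary = 0)
  mirror <- 2:ceiling(n / 2)
  X[n - mirror + 2] <- Conj(X[mirror])
  y <- Re(fft(X, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

# Band-limited component: brick-wall filter white Gaussian noise in the
# frequency domain to [center - bw/2, center + bw/2], rescale to target rms.
# bandwidth 0 degenerates to a pure sinusoid with uniform random phase.
component_signal <- function(n, fs, comp) {
  if (comp$rms_uv == 0) return(numeric(n))
  if (comp$bandwidth_hz == 0) {
    phi <- runif(1, 0, 2 * pi)
    amp <- comp$rms_uv * sqrt(2)
    return(amp * cos(2 * pi * comp$center_hz * (0:(n - 1)) / fs + phi))
  }
  x <- rnorm(n)
  X <- fft(x)
  nhalf <- floor(n / 2) + 1L
  f <- (seq_len(nhalf) - 1) * fs / n
  lo <- max(comp$center_hz - comp$bandwidth_hz / 2, fs / n)
  hi <- min(comp$center_hz + comp$bandwidth_hz / 2, fs / 2)
  keep <- which(f >= lo & f <= hi)
  if (length(keep) == 0L) keep <- which.min(abs(f[-1] - comp$center_hz)) + 1L
  mask <- rep(0, nhalf)
  mask[keep] <- 1
  X[seq_len(nhalf)] <- X[seq_len(nhalf)] * mask
  if (n %% 2 == 0) X[nhalf] <- complex(real = Re(X[nhalf]), imaginary = 0)
  mirror <- 2:ceiling(n / 2)
  X[n - mirror + 2] <- Conj(X[mirror])
  y <- Re(fft(X, inverse = TRUE)) / n
  y * comp$rms_uv / sqrt(mean(y^2))
}

# power gain applied to a component in the after phase (product over all
# modulated bands whose interval contains the component centre)
component_gain <- function(comp, modulation) {
  bg <- modulation$band_gains
  hit <- bg$f_lo_hz <= comp$center_hz & comp$center_hz <= bg$f_hi_hz
  if (!any(hit)) return(1)
  prod(bg$gain[hit])
}

#' Generate one synthetic EPG recording
#'
#' Deterministic given `(base_seed, replicate_index, phase)`: the recording
#' seed is `base_seed + 10007 * replicate_index + (phase == "after")`. The
#' signal is the sum of a spectrally shaped 1/f^beta Gaussian background and
#' the configured band-limited components; when `phase = "after"` and the
#' configuration carries a [step_modulation()], in-band component amplitudes
#' are scaled by `sqrt(gain)` from the onset sample onward.
#'
#' @param config A [generator_config()].
#' @param replicate_index Zero-based replicate index in `[0, n_replicates)`.
#' @param phase `"before"` or `"after"`.
#' @param treatment Treatment label stored on the recording.
#' @return An [epg_recording()] with exactly `round(fs * duration_s)` samples.
#' @export
generate_recording <- function(config, replicate_index, phase = c("before", "after"),
                               treatment = "synthetic") {
  if (!inherits(config, "epg_generator_config")) {
    stop_electrome("`config` must be created by generator_config()", "config")
  }
  phase <- match.arg(phase)
  if (!is.numeric(replicate_index) || length(replicate_index) != 1L ||
      replicate_index != round(replicate_index) ||
      replicate_index < 0 || replicate_index >= config$n_replicates) {
    stop_electrome(sprintf(
      "invalid value for field `replicate_index`: must be an integer in [0, %d)",
      config$n_replicates), "config")
  }
  n <- round(config$fs * config$duration_s)
  seed <- recording_seed(config, replicate_index, phase)
  samples <- withr::with_seed(
    seed,
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection",
    {
      sig <- shaped_background(n, config$fs, config$background_exponent,
                               config$background_rms)
      for (comp in config$components) {
        y <- component_signal(n, config$fs, comp)
        if (identical(phase, "after") && !is.null(config$modulation)) {
          g <- component_gain(comp, config$modulation)
          if (g != 1) {
            i0 <- floor(config$modulation$onset_s * config$fs) + 1
            if (i0 <= n) y[i0:n] <- y[i0:n] * sqrt(g)
          }
        }
        sig <- sig + y
      }
      sig
    }
  )
  epg_recording(samples, fs = config$fs,
                plant_id = sprintf("plant%02d", replicate_index + 1),
                treatment = treatment, phase = phase)
}

#' Generate a replicate cohort (both phases)
#'
#' Produces `n_replicates` recordings for each of the before and after phases.
#' Per-recording seeds are derived from `base_seed` so cohorts are exactly
#' reproducible while replicates and phases remain mutually independent.
#'
#' @param config A [generator_config()].
#' @param treatment Treatment label applied to every recording.
#' @return A tibble with columns `plant_id`, `treatment`, `phase`, `fs` and a
#'   list-column `recording` of [epg_recording()] objects.
#' @export
generate_cohort <- function(config, treatment = "synthetic") {
  if (!inherits(config, "epg_generator_config")) {
    stop_electrome("`config` must be created by generator_config()", "config")
  }
  grid <- tidyr::expand_grid(phase = c("before", "after"),
                             replicate_index = seq_len(config$n_replicates) - 1L)
  recs <- pmap(grid, function(phase, replicate_index) {
    generate_recording(config, replicate_index, phase, treatment = treatment)
  })
  tibble(
    plant_id = map_chr_local(recs, "plant_id"),
    treatment = treatment,
    phase = grid$phase,
    fs = config$fs,
    recording = recs
  )
}

map_chr_local <- function(x, field) vapply(x, function(el) el[[field]], character(1))

#' Serialize / read a generator configuration as JSON
#'
#' The JSON schema shipped at `system.file("schema",
#' "generator_config.schema.json", package = "electrome")` documents the
#' format.
#'
#' @param config A [generator_config()].
#' @param path Destination (for write) or source (for read) JSON file.
#' @return `read_generator_config()` returns a [generator_config()];
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  if (!inherits(config, "epg_generator_config")) {
    stop_electrome("`config` must be created by generator_config()", "config")
  }
  out <- list(
    fs = config$fs, duration_s = config$duration_s,
    n_replicates = config$n_replicates,
    background_exponent = config$background_exponent,
    background_rms = config$background_rms,
    components = lapply(config$components, function(cp) {
      list(center_hz = cp$center_hz, bandwidth_hz = cp$bandwidth_hz,
           rms_uv = cp$rms_uv)
    }),
    base_seed = config$base_seed
  )
  if (!is.null(config$modulation)) {
    bg <- config$modulation$band_gains
    out$modulation <- list(
      onset_s = config$modulation$onset_s,
      band_gains = stats::setNames(as.list(bg$gain), bg$name),
      bands = lapply(seq_len(nrow(bg)), function(i) {
        list(name = bg$name[i], f_lo_hz = bg$f_lo_hz[i], f_hi_hz = bg$f_hi_hz[i])
      })
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    stop_electrome(sprintf("generator config not found: %s", path), "missing_file")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  comps <- lapply(raw$components %||% list(), function(cp) {
    oscillatory_component(cp$center_hz, cp$bandwidth_hz %||% 0, cp$rms_uv)
  })
  modulation <- NULL
  if (!is.null(raw$modulation)) {
    m <- raw$modulation
    gains <- unlist(m$band_gains)
    bands <- if (!is.null(m$bands)) {
      list_rbind(map(m$bands, as_tibble))
    } else {
      default_bands()
    }
    modulation <- step_modulation(m$onset_s %||% 1200, gains, bands = bands)
  }
  generator_config(
    fs = raw$fs %||% 62.5, duration_s = raw$duration_s %||% 7200,
    n_replicates = raw$n_replicates %||% 23,
    background_exponent = raw$background_exponent %||% 1,
    background_rms = raw$background_rms %||% 20,
    components = comps, modulation = modulation,
    base_seed = raw$base_seed %||% 1L
  )
}
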