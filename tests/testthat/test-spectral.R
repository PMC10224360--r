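fs <- 62.5

test_that("minute segmentation drops the trailing partial window", {
  x <- rnorm(450000)
  wins <- segment_minutes(x, 60, fs = fs)
  expect_length(wins, 120L)
  expect_true(all(lengths(wins) == 3750L))
  expect_identical(wins[[1]], x[1:3750])
  expect_identical(wins[[120]], x[(450000 - 3749):450000])

  expect_length(segment_minutes(rnorm(3750), 60, fs = fs), 1L)
  expect_error(segment_minutes(rnorm(3749), 60, fs = fs),
               class = "electrome_error_too_short")
})

test_that("mean frequency locates tones and their power-weighted mixtures", {
  t <- (0:3749) / fs
  bin <- 1 / 60
  expect_equal(mean_frequency(sin(2 * pi * 5 * t), fs), 5, tolerance = bin / 5)
  two <- sin(2 * pi * 2 * t) + sin(2 * pi * 8 * t + 1)
  expect_equal(mean_frequency(two, fs), 5, tolerance = bin / 5)
  expect_equal(mean_frequency(two, fs, mode = "magnitude_mean"), 5,
               tolerance = bin / 5)
  # detrending: an added offset must not move the centroid
  expect_equal(mean_frequency(two + 100, fs), mean_frequency(two, fs))
  expect_error(mean_frequency(rep(3, 100), fs),
               class = "electrome_error_undefined_centroid")
})

test_that("white-noise centroid sits at fs/4, the flat-spectrum mean", {
  withr::with_seed(5, {
    mf <- mean_frequency(rnorm(3750), fs)
  })
  expect_equal(mf, fs / 4, tolerance = 0.05)
})

test_that("mean DDP is the raw window mean", {
  expect_identical(mean_ddp(c(1, 2, 3)), 2)
  expect_identical(mean_ddp(rep(17, 10)), 17)
  t <- (0:3749) / fs
  expect_equal(mean_ddp(30 * sin(2 * pi * 0.5 * t)), 0, tolerance = 1e-9)
  expect_error(mean_ddp(numeric(0)), class = "electrome_error_bad_window")
})

test_that("the Welch grid matches its segment length and the density is one-sided", {
  x <- withr::with_seed(7, rnorm(fs * 60))
  psd <- welch_psd(x, fs)
  expect_length(psd$freqs_hz, 126L)  # nperseg/2 + 1 for 4 s segments
  expect_equal(diff(psd$freqs_hz)[1], 0.25)
  expect_equal(max(psd$freqs_hz), 31.25)
  expect_identical(psd$n_segments, 29L)
  expect_true(all(psd$density >= 0))

  expect_true(all(welch_psd(rep(0, 1000), fs)$density == 0))
  expect_error(welch_psd(rnorm(100), fs), class = "electrome_error_too_short")
})

test_that("the Welch density integrates to the variance of white noise", {
  x <- withr::with_seed(8, rnorm(fs * 300))
  psd <- welch_psd(x, fs)
  expect_equal(sum(psd$density) * 0.25, var(x), tolerance = 0.05)
})

test_that("the spectrum underlying the centroid matches a direct DFT", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(16:1024, 1)
      x <- rnorm(n)
      got <- electrome:::rfft_power(x, fs)$power
      want <- naive_dft_power(x)
      expect_lt(max(abs(got - want)) / max(want), 1e-9)
    }
  })
})

test_that("Simpson band integration is exact for a linear density", {
  f <- seq(0, 31.25, by = 0.25)
  psd <- psd_estimate(f, f)  # density equal to frequency
  for (b in list(c(0.5, 4), c(0, 31.25), c(4, 8.25))) {
    got <- band_power(psd, list(name = "b", f_lo_hz = b[1], f_hi_hz = b[2]))
    expect_equal(got, (b[2]^2 - b[1]^2) / 2, tolerance = 1e-6)
  }
})

test_that("band power scales quadratically with amplitude", {
  x <- withr::with_seed(9, rnorm(fs * 60))
  p1 <- welch_psd(x, fs)
  p3 <- welch_psd(3 * x, fs)
  for (j in 1:7) {
    b <- default_bands()[j, ]
    if (b$f_hi_hz > 31.25) b$f_hi_hz <- 31.25
    expect_equal(band_power(p3, b), 9 * band_power(p1, b), tolerance = 1e-12)
  }
})

test_that("an on-grid tone's band power matches the periodogram oracle", {
  # A 10 uV tone at 1 Hz lies exactly on the 0.25 Hz Welch grid: its Hann
  # spectrum is a 3-bin line with relative powers 1/4, 1, 1/4. The
  # rectangle-rule integral recovers the full tone power A^2/2 = 50; the
  # composite Simpson weights (4,2,4)/3 on those bins give exactly 8/9 of it.
  tone <- 10 * cos(2 * pi * 1 * (0:449999) / fs + 0.3)
  psd <- welch_psd(tone, fs)
  rect <- sum(psd$density[psd$freqs_hz >= 0.5 & psd$freqs_hz <= 4]) * 0.25
  expect_equal(rect, 50, tolerance = 1e-6)
  delta <- band_power(psd, list(name = "delta", f_lo_hz = 0.5, f_hi_hz = 4))
  expect_equal(delta, 50 * 8 / 9, tolerance = 1e-6)  # cross-checked vs scipy
  # leakage beyond the 3-bin main lobe is numerically zero
  theta <- band_power(psd, list(name = "theta", f_lo_hz = 4, f_hi_hz = 8))
  expect_lt(theta, 0.5)
  out_of_band <- sum(psd$density[psd$freqs_hz < 0.5 | psd$freqs_hz > 4]) * 0.25
  expect_lt(out_of_band, 0.01 * 50)
})

test_that("bands reaching past the Nyquist frequency are clipped with a warning", {
  x <- withr::with_seed(10, rnorm(fs * 60))
  psd <- welch_psd(x, fs)
  gamma <- list(name = "gamma", f_lo_hz = 20, f_hi_hz = 100)
  expect_warning(full <- band_power(psd, gamma),
                 class = "electrome_warning_nyquist_clip")
  clipped <- band_power(psd, list(name = "g", f_lo_hz = 20, f_hi_hz = 31.25))
  expect_identical(full, clipped)
  expect_error(
    band_power(psd, list(name = "ultra", f_lo_hz = 40, f_hi_hz = 50)),
    "ultra", class = "electrome_error_empty_band")
})

test_that("narrow bands fall back to trapezoid integration with a warning", {
  x <- withr::with_seed(11, rnorm(fs * 60))
  psd <- welch_psd(x, fs)
  expect_warning(
    got <- band_power(psd, list(name = "sliver", f_lo_hz = 0.25, f_hi_hz = 0.6)),
    class = "electrome_warning_trapezoid_fallback")
  d <- psd$density[psd$freqs_hz %in% c(0.25, 0.5)]
  expect_equal(got, sum(d) / 2 * 0.25)
})

test_that("per-minute band power series are stationary for stationary input", {
  cfg <- tiny_config(duration_s = 600, n_replicates = 1, base_seed = 21,
                     background_exponent = 0, background_rms = 10,
                     components = list(oscillatory_component(2, 2, 10)))
  rec <- generate_recording(cfg, 0, "before")
  abp <- suppressWarnings(abp_series(rec))
  expect_identical(nrow(abp), 7L * 10L)
  expect_identical(sort(unique(abp$minute)), 0:9)
  cv <- vapply(split(abp$value, abp$feature),
               function(v) sd(v) / mean(v), numeric(1))
  expect_true(all(cv < 0.30))
})

test_that("band powers are invariant in distribution under circular shifts", {
  x <- withr::with_seed(12, rnorm(fs * 120))
  band <- list(name = "delta", f_lo_hz = 0.5, f_hi_hz = 4)
  base <- band_power(welch_psd(x, fs), band)
  shifts <- round(seq(100, length(x) - 100, length.out = 20))
  powers <- vapply(shifts, function(s) {
    y <- c(x[(s + 1):length(x)], x[1:s])
    band_power(welch_psd(y, fs), band)
  }, numeric(1))
  expect_equal(median(powers), base, tolerance = 0.05)
})
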