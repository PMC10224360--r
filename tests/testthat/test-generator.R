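test_that("recordings have exactly round(fs * duration_s) samples", {
  cfg <- tiny_config(duration_s = 120)
  rec <- generate_recording(cfg, 0, "before")
  expect_length(rec$samples, 7500L)
  expect_identical(rec$fs, 62.5)
  expect_identical(rec$phase, "before")
})

test_that("generation is deterministic given (seed, replicate, phase)", {
  cfg <- tiny_config()
  r1 <- generate_recording(cfg, 1, "after")
  r2 <- generate_recording(cfg, 1, "after")
  expect_identical(r1$samples, r2$samples)
  # different replicate or phase gives a different realization
  expect_false(identical(r1$samples, generate_recording(cfg, 0, "after")$samples))
  expect_false(identical(r1$samples, generate_recording(cfg, 1, "before")$samples))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(generate_recording(cfg, 0, "before")); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("a configuration with no sources yields an all-zero signal", {
  cfg <- tiny_config(background_rms = 0, components = list())
  rec <- generate_recording(cfg, 0, "before")
  expect_true(all(rec$samples == 0))
})

test_that("a pure tone component realizes variance A^2/2 to within 1%", {
  cfg <- tiny_config(
    duration_s = 600, background_rms = 0,
    components = list(oscillatory_component(1, 0, rms_uv = sqrt(50)))
  )
  rec <- generate_recording(cfg, 0, "before")
  expect_equal(mean(rec$samples^2), 50, tolerance = 0.01)
})

test_that("band-limited components realize the target rms and stay in band", {
  cfg <- tiny_config(
    duration_s = 600, background_rms = 0,
    components = list(oscillatory_component(5, 2, rms_uv = 12))
  )
  rec <- generate_recording(cfg, 0, "before")
  expect_equal(sqrt(mean(rec$samples^2)), 12, tolerance = 1e-9)
  psd <- welch_psd(rec$samples, rec$fs)
  inband <- band_power(psd, list(name = "in", f_lo_hz = 3.5, f_hi_hz = 6.5))
  expect_gt(inband / 144, 0.95)
})

test_that("the 1/f^beta background recovers its spectral exponent", {
  for (beta in c(0.5, 1.5)) {
    cfg <- tiny_config(duration_s = 1800, background_exponent = beta,
                       components = list(), base_seed = 31)
    rec <- generate_recording(cfg, 0, "before")
    psd <- welch_psd(rec$samples, rec$fs, window_seconds = 20)
    dat <- tidy(psd)
    dat <- dat[dat$freq_hz >= 0.1 & dat$freq_hz <= 10, ]
    slope <- unname(coef(lm(log(density_uv2_hz) ~ log(freq_hz), data = dat))[2])
    expect_equal(slope, -beta, tolerance = 0.15)
  }
})

test_that("step modulation scales in-band component power by the gain", {
  g <- 4
  cfg <- tiny_config(
    duration_s = 1200, background_rms = 0,
    components = list(oscillatory_component(2, 2, rms_uv = 10)),
    modulation = step_modulation(onset_s = 600, band_gains = c(delta = g))
  )
  rec <- generate_recording(cfg, 0, "after")
  n_on <- 600 * 62.5
  band <- list(name = "delta", f_lo_hz = 0.5, f_hi_hz = 4)
  pre <- band_power(welch_psd(rec$samples[1:n_on], 62.5), band)
  post <- band_power(welch_psd(rec$samples[(n_on + 1):length(rec$samples)], 62.5), band)
  expect_equal(post / pre, g, tolerance = 0.10)
  # the before phase is never modulated
  bef <- generate_recording(cfg, 0, "before")
  expect_equal(mean(bef$samples^2), 100, tolerance = 1e-6)
})

test_that("cohorts are reproducible and sized n_replicates per phase", {
  cfg <- tiny_config(n_replicates = 3)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(nrow(co1), 6L)
  expect_identical(table(co1$phase), table(factor(rep(c("after", "before"), each = 3))))
  expect_identical(
    lapply(co1$recording, `[[`, "samples"),
    lapply(co2$recording, `[[`, "samples")
  )
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(generator_config(fs = 0), "fs", class = "electrome_error_config")
  expect_error(generator_config(duration_s = -5), "duration_s",
               class = "electrome_error_config")
  expect_error(generator_config(n_replicates = 0), "n_replicates",
               class = "electrome_error_config")
  expect_error(generator_config(background_rms = -1), "background_rms",
               class = "electrome_error_config")
  expect_error(generator_config(background_exponent = -0.5),
               "background_exponent", class = "electrome_error_config")
  expect_error(oscillatory_component(-1, 0, 1), "center_hz",
               class = "electrome_error_config")
  expect_error(
    generator_config(components = list(oscillatory_component(40, 0, 1))),
    "center_hz", class = "electrome_error_config")
  expect_error(step_modulation(onset_s = -1), "onset_s",
               class = "electrome_error_config")
  expect_error(step_modulation(band_gains = c(low = -2)), "band_gains",
               class = "electrome_error_config")
  expect_error(step_modulation(band_gains = c(nosuch = 2)), "band_gains",
               class = "electrome_error_config")
  expect_error(
    generator_config(duration_s = 60,
                     modulation = step_modulation(onset_s = 120)),
    "onset_s", class = "electrome_error_config")
  expect_error(generate_recording(tiny_config(), 5, "before"),
               "replicate_index", class = "electrome_error_config")
})

test_that("generator configs round-trip through JSON", {
  cfg <- generator_config(
    fs = 50, duration_s = 240, n_replicates = 4, background_exponent = 0.8,
    background_rms = 12,
    components = list(oscillatory_component(0.3, 0.4, 25),
                      oscillatory_component(5, 0, 3)),
    modulation = step_modulation(onset_s = 60, band_gains = c(low = 2.5)),
    base_seed = 77
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back[c("fs", "duration_s", "n_replicates", "background_exponent",
                      "background_rms", "base_seed")],
               cfg[c("fs", "duration_s", "n_replicates", "background_exponent",
                     "background_rms", "base_seed")])
  expect_equal(back$components, cfg$components)
  expect_equal(back$modulation$onset_s, cfg$modulation$onset_s)
  expect_equal(back$modulation$band_gains$gain, cfg$modulation$band_gains$gain)
  r1 <- generate_recording(cfg, 0, "after")
  r2 <- generate_recording(back, 0, "after")
  expect_identical(r1$samples, r2$samples)
})
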