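test_that("trial_config validates its invariants", {
  expect_error(trial_config(duration = 0), "duration")
  expect_error(trial_config(eeg_rate = -1), "rates")
  expect_error(trial_config(band_amplitudes = c(alpha1 = -5)), "non-negative")
  expect_error(trial_config(band_amplitudes = c(zeta = 1)), "unknown band")
  expect_error(trial_config(asym_ratios = c(alpha1 = 0)), "positive")
  expect_error(trial_config(duration = 60, scr_times = 70), "0, duration")
  expect_error(trial_config(tonic_level = -1), "non-negative")
  expect_error(
    generate_eeg(trial_config(
      eeg_rate = 64,
      band_amplitudes = c(gamma = 2))),   # 38 Hz synthesis above 32 Hz Nyquist
    "Nyquist")
  amp <- matrix(5, 1, 1, dimnames = list("Xz", "alpha1"))
  expect_error(trial_config(band_amplitudes = amp), "unknown channel")
})

test_that("EEG generator produces calibrated deterministic oscillations", {
  # pure 10-ish Hz component: alpha1 sinusoid of amplitude a has RMS a/sqrt(2)
  amp <- matrix(10, 1, 1, dimnames = list("O1", "alpha1"))
  cfg <- quiet_config(duration = 10, band_amplitudes = amp, noise_sd = 0)
  eeg <- generate_eeg(cfg)
  expect_equal(nrow(eeg$values), 5120)           # 10 s at 512 Hz
  expect_equal(rms(eeg$values[, "O1"]), 10 / sqrt(2), tolerance = 1e-3)
  expect_true(all(eeg$values[, setdiff(eeg$labels, "O1")] == 0))

  # same seed => bit-identical; different seed => different noise
  cfg2 <- quiet_config(duration = 5, noise_sd = 3, seed = 42)
  expect_identical(generate_eeg(cfg2)$values, generate_eeg(cfg2)$values)
  cfg3 <- quiet_config(duration = 5, noise_sd = 3, seed = 43)
  expect_false(identical(generate_eeg(cfg2)$values, generate_eeg(cfg3)$values))
})

test_that("symmetric noise-only generation has unit left-right alpha ratio", {
  ratios <- vapply(1:20, function(s) {
    cfg <- quiet_config(duration = 8, channel_labels = c("F3", "F4"),
                        band_amplitudes = c(alpha1 = 0), noise_sd = 5,
                        seed = s)
    eeg <- generate_eeg(cfg)
    p <- band_power(eeg, default_bands(subbands = FALSE)["alpha"])
    mean(p$power[, "F3", "alpha"]) / mean(p$power[, "F4", "alpha"])
  }, numeric(1))
  expect_equal(mean(log(ratios)), 0, tolerance = 0.15)
})

test_that("injected hemispheric ratios are recovered from the synthesis", {
  for (r in c(1 / 8, 1 / 2, 2, 8)) {
    cfg <- quiet_config(duration = 24, channel_labels = c("F3", "F4"),
                        asym_ratios = c(alpha1 = r, alpha2 = r),
                        noise_sd = 0.5, seed = 5)
    p <- band_power(generate_eeg(cfg), default_bands(subbands = FALSE)["alpha"])
    est <- mean(log(p$power[, "F3", "alpha"]) - log(p$power[, "F4", "alpha"]))
    expect_equal(est, log(r), tolerance = 0.1 * abs(log(r)))
  }
})

test_that("EDA generator honors tonic, SCR count and determinism", {
  cfg <- quiet_config(duration = 30, tonic_level = 2.5, tonic_drift = 0)
  res <- generate_eda(cfg)
  expect_equal(as.numeric(res$eda$values), rep(2.5, 480))
  expect_equal(res$truth$scr_count, 0)

  cfg3 <- quiet_config(duration = 60, scr_times = c(5, 20, 40),
                       scr_amplitudes = c(0.2, 0.3, 0.25))
  res3 <- generate_eda(cfg3)
  expect_equal(res3$truth$scr_count, 3)
  expect_equal(res3$truth$injected$amps, c(0.2, 0.3, 0.25))
  # the first injected SCR raises the signal by its configured peak amplitude
  # (window confined to before the second onset at 20 s)
  expect_equal(max(res3$eda$values[1:280, 1]) - 2, 0.2, tolerance = 0.02)

  cfgn <- trial_config(duration = 30, seed = 9)
  expect_identical(generate_eda(cfgn)$eda$values, generate_eda(cfgn)$eda$values)
})

test_that("IBI generator matches its analytic RMSSD", {
  cfg0 <- quiet_config(duration = 40, ibi_jitter_sd = 0)
  expect_equal(rmssd(generate_ibi(cfg0)), 0)

  # alternating test mode m+d, m-d, ... has RMSSD exactly 2d
  cfga <- quiet_config(duration = 40, ibi_jitter_sd = 15,
                       ibi_mode = "alternating")
  ibi <- generate_ibi(cfga)
  expect_equal(unique(round(ibi$ibi_ms)), c(815, 785))
  expect_equal(rmssd(ibi), 30)

  # beat count: 80 s at 800 ms mean => 100 +/- 2 beats
  cfgb <- quiet_config(duration = 80, mean_ibi = 800, ibi_jitter_sd = 20)
  expect_lt(abs(length(generate_ibi(cfgb)$ibi_ms) - 100), 2.5)

  expect_error(generate_ibi(quiet_config(mean_ibi = 100, ibi_jitter_sd = 90)),
               "non-positive")
})

test_that("generate_trial writes a re-readable container with ground truth", {
  dir <- withr::local_tempdir()
  cfg <- quiet_config(duration = 20, seed = 11)
  res <- generate_trial(cfg, dir)
  expect_true(all(file.exists(unlist(res$paths))))

  streams <- read_container(res$paths$container)
  eeg <- generate_eeg(cfg)
  expect_equal(unname(streams$eeg$values), unname(eeg$values))
  expect_equal(streams$eeg$timestamps, cfg$start_epoch +
                 (seq_len(nrow(eeg$values)) - 1) / 512)
  expect_equal(streams$eeg$labels, default_montage())

  ann <- read.csv(res$paths$annotations)
  expect_equal(nrow(ann), nrow(cfg$event_schedule))

  truth <- jsonlite::read_json(res$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$rmssd_analytic, sqrt(2) * cfg$ibi_jitter_sd)

  # identical config + seed => identical files (bitwise payloads)
  dir2 <- withr::local_tempdir()
  generate_trial(cfg, dir2)
  s2 <- read_container(file.path(dir2, "streams.h5"))
  expect_identical(streams$eeg$values, s2$eeg$values)
  expect_identical(streams$eda$values, s2$eda$values)

  # a schedule without Stop is rejected before anything is written
  bad <- quiet_config(duration = 20,
                      event_schedule = data.frame(event = "Start", time = 0))
  expect_error(generate_trial(bad, withr::local_tempdir()), "Stop")
})
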