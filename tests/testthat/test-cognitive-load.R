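test_that("band power is amplitude-calibrated and band-selective", {
  rec <- make_tone(9, dur = 10)
  p <- band_power(rec, bands_no_delta())
  expect_equal(mean(p$power[, 1, "alpha1"]), 0.5, tolerance = 0.05)
  tot <- apply(p$power[, 1, c("theta", "alpha", "beta", "gamma")], 1, sum)
  expect_gt(mean(p$power[, 1, "alpha1"]) / mean(tot), 0.9)

  zero <- eeg_recording(matrix(0, 4096, 1), labels = "Cz")
  pz <- band_power(zero, bands_no_delta())
  expect_true(all(pz$power == 0))

  # white noise: band power proportional to bandwidth
  set.seed(11)
  wn <- eeg_recording(matrix(rnorm(512 * 30), ncol = 1), labels = "Cz")
  pw <- band_power(wn, bands_no_delta())
  dens <- vapply(c("theta", "alpha", "beta", "gamma"), function(b) {
    bd <- bands_no_delta()[[b]]
    mean(pw$power[, 1, b]) / (bd$hi - bd$lo)
  }, numeric(1))
  expect_lt((max(dens) - min(dens)) / mean(dens), 0.3)

  expect_error(band_power(make_tone(9, dur = 1), bands_no_delta(),
                          window = 2), "longer than recording")
})

test_that("asymmetry index matches its closed form and its symmetries", {
  expect_equal(asymmetry_index(exp(2), exp(1)), 0.43229, tolerance = 1e-4)
  expect_equal(asymmetry_index(5, 5), 0)
  set.seed(21)
  a <- exp(runif(100, -2, 5)); b <- exp(runif(100, -2, 5))
  expect_equal(asymmetry_index(a, b), -asymmetry_index(b, a))
  expect_error(asymmetry_index(-1, 2), "positive")
  # total power near 1 muV^2: the log denominator vanishes -> invalid window
  expect_true(is.na(asymmetry_index(0.5, 0.5)))
})

test_that("asymmetry index is NOT scale invariant (regression pin)", {
  ai1 <- asymmetry_index(8, 2)
  ai2 <- asymmetry_index(80, 20)
  expect_false(isTRUE(all.equal(ai1, ai2)))
  expect_equal(ai1, log(4) / log(10), tolerance = 1e-12)
  expect_equal(ai2, log(4) / log(100), tolerance = 1e-12)
})

test_that("cognitive-load index is -|AI| and tracks injected asymmetry", {
  rec <- generate_eeg(quiet_config(duration = 20,
                                   channel_labels = c("F3", "F4"),
                                   noise_sd = 1, seed = 4))
  p <- band_power(rec, bands_no_delta())
  asym <- asymmetry_series(p, "F3", "F4", "alpha")
  cl <- cl_index(asym)
  expect_equal(cl$cl, -abs(asym$ai))
  expect_true(all(cl$cl <= 0, na.rm = TRUE))

  # ratio 4 vs ratio 1: mean CL strictly more negative under the ratio
  mean_cl <- function(r, seed) {
    cfg <- quiet_config(duration = 20, channel_labels = c("F3", "F4"),
                        asym_ratios = c(alpha1 = r, alpha2 = r),
                        noise_sd = 1, seed = seed)
    p <- band_power(generate_eeg(cfg), bands_no_delta())
    mean(cl_index(asymmetry_series(p, "F3", "F4", "alpha"))$cl, na.rm = TRUE)
  }
  expect_lt(mean_cl(4, 7), mean_cl(1, 7))

  occ <- asymmetry_series(p, "F3", "F4", "alpha")
  attr(occ, "pair") <- c("O1", "O2")
  expect_error(cl_index(occ), "frontal")
  expect_error(asymmetry_series(p, "F4", "F3", "alpha"), "homologous")
})

test_that("injected left:right ratios are recovered as ln-ratios", {
  for (r in c(1 / 4, 1 / 2, 1, 2, 4)) {
    errs <- vapply(1:3, function(seed) {
      cfg <- quiet_config(duration = 24, channel_labels = c("F3", "F4"),
                          asym_ratios = c(alpha1 = r, alpha2 = r),
                          noise_sd = 0.5, seed = seed)
      p <- band_power(generate_eeg(cfg), bands_no_delta())
      expect_gte(length(p$center), 20)
      est <- mean(log(p$power[, "F3", "alpha"]) -
                    log(p$power[, "F4", "alpha"]))
      est - log(r)
    }, numeric(1))
    tol <- if (r == 1) 0.05 else 0.1 * abs(log(r))
    expect_lt(max(abs(errs)), tol)
  }
})

test_that("total CL measures log power relative to rest", {
  rest <- generate_eeg(quiet_config(duration = 16, noise_sd = 1, seed = 6))
  p_rest <- band_power(rest, bands_no_delta())
  # task power == resting power -> TCL 0
  expect_equal(total_cl(p_rest, "O1", p_rest), 0)
  # task power = e * resting power -> TCL 1 (natural-log units)
  task <- rest
  task$values <- rest$values * sqrt(exp(1))
  p_task <- band_power(task, bands_no_delta())
  expect_equal(total_cl(p_task, "O1", p_rest), 1, tolerance = 1e-10)
  expect_error(total_cl(p_task, "Oz", p_rest), "Oz")
})

test_that("global CL summarises the electrode distribution", {
  ds <- navload:::distribution_summary(c(1, 2, 3, 4, 5))
  expect_equal(ds$median, 3)
  expect_equal(ds$q1, 2)
  expect_equal(ds$q3, 4)
  expect_equal(ds$whisker_lo, 1)
  expect_equal(ds$whisker_hi, 5)
  expect_equal(ds$skewness, 0)

  rest <- generate_eeg(quiet_config(duration = 12, noise_sd = 1, seed = 9))
  p <- band_power(rest, bands_no_delta())
  g <- global_cl(p, p)
  expect_equal(unname(g$tcl), rep(0, 16))
  expect_equal(g$summary$iqr, 0)
})

test_that("the upper envelope dominates the series and carries markers", {
  centers <- seq(0.5, 59.5, by = 0.5)
  const <- structure(data.frame(center = centers, ai = rep(0.3, length(centers)),
                                valid = TRUE),
                     pair = c("F3", "F4"), band = "alpha1",
                     class = c("asymmetry_series", "data.frame"))
  env <- asymmetry_envelope(const)
  expect_equal(env$envelope, rep(0.3, length(centers)))

  # modulated series: envelope tracks the slow modulator away from edges
  # (carrier chosen so its peaks fall exactly on window centers)
  mod <- 2 + sin(2 * pi * centers / 30)
  carrier <- abs(sin(pi * centers))
  series <- const
  series$ai <- mod * carrier
  env2 <- asymmetry_envelope(series)
  interior <- centers > 5 & centers < 55
  expect_lt(max(abs(env2$envelope[interior] - mod[interior]) / mod[interior]),
            0.05)
  # envelope >= series at every local-max support point
  expect_true(all(env2$envelope >= series$ai - 1e-9))

  log <- event_log(c("Start", "Collision", "Stop"), c(0, 17.2, 60))
  env3 <- asymmetry_envelope(const, log)
  mk <- attr(env3, "markers")
  expect_equal(nrow(mk), 1)
  expect_equal(mk$center, 17)   # nearest window center

  expect_error(asymmetry_envelope(const[1:2, ]), "3 valid windows")
})

test_that("visual-cortex asymmetry recovers the injected O1:O2 ratio", {
  cfg <- quiet_config(duration = 24, channel_labels = c("O1", "O2"),
                      asym_ratios = c(delta = 6, theta = 6, alpha1 = 6,
                                      alpha2 = 6, beta = 6, gamma = 6),
                      noise_sd = 0.5, seed = 3)
  p <- bp(generate_eeg(cfg))
  vc <- vc_asymmetry(p)
  expect_equal(vc$ln_ratio_mean, log(6), tolerance = 0.1 * log(6))
  expect_true(all(vc$asym$ai[vc$asym$valid] > 0))

  # swapping the hemispheres flips the sign exactly
  cfg_swap <- quiet_config(duration = 24, channel_labels = c("O1", "O2"),
                           asym_ratios = c(delta = 1 / 6, theta = 1 / 6,
                                           alpha1 = 1 / 6, alpha2 = 1 / 6,
                                           beta = 1 / 6, gamma = 1 / 6),
                           noise_sd = 0.5, seed = 3)
  vc2 <- vc_asymmetry(bp(generate_eeg(cfg_swap)))
  expect_equal(vc2$ln_ratio_mean, -log(6), tolerance = 0.1 * log(6))

  # equal powers -> zero asymmetry
  cfg_eq <- quiet_config(duration = 12, channel_labels = c("O1", "O2"),
                         noise_sd = 0, seed = 5)
  vc3 <- vc_asymmetry(bp(generate_eeg(cfg_eq)))
  expect_equal(vc3$ln_ratio_mean, 0, tolerance = 1e-6)

  p_no_o2 <- bp(generate_eeg(quiet_config(duration = 8,
                                          channel_labels = c("O1", "F3"))))
  expect_error(vc_asymmetry(p_no_o2), "O2")

  rest <- bp(generate_eeg(quiet_config(duration = 12,
                                       channel_labels = c("O1", "O2"),
                                       noise_sd = 0.5, seed = 8)))
  vc4 <- vc_asymmetry(p, resting = rest)
  expect_named(vc4$tcl, c("O1", "O2"))
})
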