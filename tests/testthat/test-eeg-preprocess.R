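test_that("broadband band-pass passes 10 Hz, kills 200 Hz and DC", {
  tone10 <- make_tone(10, dur = 4)
  out10 <- eeg_bandpass(tone10)
  mid <- 512:(nrow(out10$values) - 512)      # clear of filter edge transients
  expect_lt(abs(db_ratio(out10$values[mid, 1], tone10$values[mid, 1])), 1)

  tone200 <- make_tone(200, dur = 4)
  out200 <- eeg_bandpass(tone200)
  expect_lt(db_ratio(out200$values[mid, 1], tone200$values[mid, 1]), -30)

  # DC rejection: away from the high-pass startup transient the constant
  # signal is suppressed to well under 1% of its value
  dc <- eeg_recording(matrix(5, 512 * 20, 1), labels = "Cz")
  expect_lt(max(abs(eeg_bandpass(dc)$values[(512 * 8):(512 * 12), 1])), 0.05)

  expect_error(eeg_bandpass(tone10, lo = 0), "corner")
  expect_error(eeg_bandpass(tone10, lo = 1, hi = 300), "corner")
})

test_that("notch removes 50 Hz but spares 45 Hz", {
  mid <- 512:1536
  t50 <- make_tone(50, dur = 4)
  expect_lt(db_ratio(eeg_notch(t50)$values[mid, 1], t50$values[mid, 1]), -30)
  t45 <- make_tone(45, dur = 4)
  expect_lt(abs(db_ratio(eeg_notch(t45)$values[mid, 1], t45$values[mid, 1])), 1)
  zero <- eeg_recording(matrix(0, 2048, 1), labels = "Cz")
  expect_equal(eeg_notch(zero)$values, zero$values)
})

test_that("filters are linear", {
  set.seed(3)
  x <- make_tone(c(6, 21), amps = c(3, 2), dur = 3)
  y <- make_tone(c(11, 2.5), amps = c(1, 4), dur = 3, phase = 1)
  mix <- x; mix$values <- 2 * x$values - 3 * y$values
  lhs <- eeg_bandpass(mix)$values
  rhs <- 2 * eeg_bandpass(x)$values - 3 * eeg_bandpass(y)$values
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("artifact suppression flags brief transients and nothing else", {
  fs <- 512
  t <- (seq_len(10 * fs) - 1) / fs
  clean <- 10 * sin(2 * pi * 10 * t)
  rec_clean <- eeg_recording(cbind(clean), labels = "Fp1")
  res_clean <- remove_artifacts(rec_clean)
  expect_equal(sum(res_clean$mask), 0)
  expect_equal(res_clean$rec$values[, 1], clean)  # unflagged samples untouched

  blink <- ifelse(t >= 5 & t < 5.05,
                  200 * 0.5 * (1 - cos(2 * pi * (t - 5) / 0.05)), 0)
  rec <- eeg_recording(cbind(clean + blink), labels = "Fp1")
  res <- remove_artifacts(rec)
  idx <- which(blink > 0)
  expect_true(any(res$mask[idx, 1]))
  # residual versus the blink-free signal stays below 10% of blink amplitude
  expect_lt(max(abs(res$rec$values[idx, 1] - clean[idx])), 20)
  # unflagged samples pass through bit-identically
  expect_equal(res$rec$values[!res$mask[, 1], 1], (clean + blink)[!res$mask[, 1]])

  res2 <- remove_artifacts(rec)
  expect_identical(res$mask, res2$mask)

  expect_error(remove_artifacts(rec, window = 0.002), "degenerate window")
})

test_that("band decomposition concentrates tones in their bands", {
  share <- function(freq, band_name) {
    rec <- make_tone(freq, dur = 4)
    decomp <- band_decompose(rec)
    pows <- vapply(decomp, function(r) mean(r$values[512:1536, 1]^2),
                   numeric(1))
    # alpha aliases its sub-bands; count each physical band once
    pows[band_name] / sum(pows[setdiff(names(pows), c("alpha1", "alpha2"))])
  }
  expect_gt(share(9, "alpha1"), 0.9)
  expect_gt(share(11.5, "alpha2"), 0.9)

  mix <- make_tone(c(2, 20), amps = c(4, 2), dur = 6)
  decomp <- band_decompose(mix, default_bands(subbands = FALSE))
  mid <- 1024:(nrow(mix$values) - 1024)
  expect_equal(mean(decomp$delta$values[mid, 1]^2), 4^2 / 2, tolerance = 0.1)
  expect_equal(mean(decomp$beta$values[mid, 1]^2), 2^2 / 2, tolerance = 0.1)

  bad <- list(band_definition("a", 4, 10), band_definition("b", 8, 14))
  expect_error(band_decompose(mix, bad), "overlap")
})

test_that("disjoint bands reconstruct a multi-tone signal", {
  rec <- make_tone(c(2, 6, 9, 20, 38), amps = c(4, 3, 3, 2, 1), dur = 6)
  decomp <- band_decompose(rec, default_bands(subbands = FALSE))
  total <- Reduce(`+`, lapply(decomp, `[[`, "values"))
  ref <- eeg_bandpass(rec, 0.5, 45)$values
  mid <- 1024:(nrow(ref) - 1024)
  expect_lt(rms(total[mid, 1] - ref[mid, 1]) / rms(ref[mid, 1]), 0.1)
})

test_that("baseline normalization subtracts the resting mean per channel", {
  set.seed(8)
  rest <- eeg_recording(matrix(rnorm(2048 * 2, mean = c(1, -2)), 2048, 2,
                               byrow = TRUE), labels = c("F3", "F4"))
  task <- rest
  task$values <- sweep(rest$values, 2, c(3, 5), `+`)   # task = rest + c
  norm <- baseline_normalize(task, rest, mode = "literal")
  expect_equal(unname(colMeans(norm$values)), c(3, 5), tolerance = 1e-10)

  # power mode: a reference normalized against itself has per-channel mean 0
  rec <- generate_eeg(quiet_config(duration = 10,
                                   channel_labels = c("F3", "F4"), seed = 2))
  p <- band_power(rec, bands_no_delta())
  selfnorm <- baseline_normalize(p, p)
  expect_true(isTRUE(selfnorm$log_relative))
  for (b in c("alpha", "beta"))
    expect_equal(unname(colMeans(selfnorm$power[, , b])), c(0, 0),
                 tolerance = 1e-10)

  rest_small <- eeg_recording(rest$values[, 1, drop = FALSE], labels = "F3")
  expect_error(baseline_normalize(task, rest_small, mode = "literal"), "F4")
})
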