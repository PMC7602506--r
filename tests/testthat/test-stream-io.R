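make_streams <- function(dur = 10, fs = 64, nch = 2) {
  n <- dur * fs
  timestamped_stream("eeg", fs, (seq_len(n) - 1) / fs,
                     matrix(sin(seq_len(n * nch)), ncol = nch),
                     paste0("ch", seq_len(nch)))
}

test_that("stream invariants are enforced", {
  expect_error(timestamped_stream("x", 10, c(0, 2, 1), matrix(1:3), "a"),
               "monotone")
  expect_error(timestamped_stream("x", 10, 0:1, matrix(1:3), "a"),
               "timestamps length")
  # 2% spacing error against the nominal rate
  expect_error(timestamped_stream("x", 100, seq(0, 1.02, length.out = 101),
                                  matrix(rnorm(101)), "a"),
               "inconsistent with nominal rate")
})

test_that("container write/read round-trip is lossless", {
  path <- withr::local_tempfile(fileext = ".h5")
  s <- make_streams()
  write_container(list(s), path)
  back <- read_container(path)
  expect_equal(back$eeg$values, s$values)
  expect_equal(back$eeg$timestamps, s$timestamps)
  expect_equal(back$eeg$nominal_rate, s$nominal_rate)
  expect_equal(back$eeg$labels, s$labels)
})

test_that("malformed containers are rejected with the offending group named", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "eda")
  rhdf5::h5write(c(0, 2, 1), path, "eda/time")   # shuffled
  rhdf5::h5write(matrix(1:3), path, "eda/values")
  fid <- rhdf5::H5Fopen(path); gid <- rhdf5::H5Gopen(fid, "eda")
  rhdf5::h5writeAttribute(16, gid, "rate_hz")
  rhdf5::h5writeAttribute("eda", gid, "labels")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  expect_error(read_container(path), "monotone")

  path2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path2)
  rhdf5::h5createGroup(path2, "hr")
  rhdf5::h5write(0:9 / 2, path2, "hr/time")
  rhdf5::h5write(matrix(rnorm(10)), path2, "hr/values")
  expect_error(read_container(path2), "'hr'.*rate_hz")

  path3 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path3)
  rhdf5::h5createGroup(path3, "eeg")
  rhdf5::h5write(0:9, path3, "eeg/time")
  expect_error(read_container(path3), "missing dataset 'values'")
})

test_that("annotation CSVs are validated on read", {
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event,timestamp", "Start,100", "Collision,110", "Find,120",
               "Lost,130", "TouchCane,140", "Stop,160"), ok)
  log <- read_annotations(ok)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 6)

  bad1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event,timestamp", "Start,0", "Jump,1", "Stop,2"), bad1)
  expect_error(read_annotations(bad1), "unknown event label.*Jump")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event,timestamp", "Start,0", "Collision,1"), bad2)
  expect_error(read_annotations(bad2), "exactly one Stop")

  bad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event,timestamp", "Stop,0", "Start,2"), bad3)
  expect_error(read_annotations(bad3), "non-decreasing|precedes")
})

test_that("alignment trims overruns and pads shortfalls to the reference", {
  fs <- 512
  long <- timestamped_stream("eeg", fs, (seq_len(12 * fs) - 1) / fs,
                             matrix(rnorm(12 * fs)), "F3")
  short <- timestamped_stream("eda", 16, (seq_len(9 * 16) - 1) / 16,
                              matrix(abs(rnorm(9 * 16))), "eda")
  res <- align_streams(list(long, short), 10)
  expect_equal(nrow(res$streams$eeg$values), 10 * fs)   # 1024 samples trimmed
  expect_equal(res$report$trimmed_s[res$report$stream == "eeg"], 2)
  expect_equal(sum(is.na(res$streams$eda$values)), 16)  # 1 s of NA padding
  expect_equal(res$report$padded_s[res$report$stream == "eda"], 1)
  expect_false(any(res$report$misaligned))

  # exact-length stream: identity, zero-trim report
  exact <- timestamped_stream("hr", 16, (seq_len(160) - 1) / 16,
                              matrix(rnorm(160)), "x")
  res2 <- align_streams(list(exact), 10)
  expect_equal(res2$streams$hr$values, exact$values)
  expect_equal(res2$report$trimmed_s + res2$report$padded_s, 0)

  # idempotence
  res3 <- align_streams(res$streams, 10)
  expect_equal(res3$streams$eeg$values, res$streams$eeg$values)
  expect_equal(sum(res3$report$trimmed_s) + sum(res3$report$padded_s), 0)

  # kept duration + trimmed duration equals max(original, reference), i.e.
  # original data + padding is conserved per stream
  for (nm in names(res$streams)) {
    kept <- nrow(res$streams[[nm]]$values) / res$streams[[nm]]$nominal_rate
    row <- res$report[res$report$stream == nm, ]
    orig <- if (nm == "eeg") 12 else 9
    expect_equal(kept + row$trimmed_s, max(orig, 10))
    expect_equal((kept - row$padded_s) + row$trimmed_s + row$padded_s,
                 max(orig, 10))
  }

  expect_error(align_streams(list(short), 100), "gross clock error")
})

test_that("slicing restricts to [Start, Stop) and re-anchors times", {
  fs <- 512
  s <- timestamped_stream("eeg", fs, 1000 + (seq_len(210 * fs) - 1) / fs,
                          matrix(rnorm(210 * fs)), "F3")
  log <- event_log(c("Start", "Collision", "Stop"), c(1002, 1010, 1206))
  res <- slice_by_events(s, log)
  expect_equal(nrow(res$stream$values), 204 * fs)
  expect_equal(res$stream$timestamps[1], 0)
  expect_equal(res$events$timestamp, c(0, 8, 204))

  log0 <- event_log(c("Start", "Stop"), c(1002, 1002))
  expect_error(slice_by_events(s, log0), "empty window")
})
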