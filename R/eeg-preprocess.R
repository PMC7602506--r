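#' Broadband band-pass filter for EEG
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero net phase shift). The default 0.5-100 Hz passband removes DC drift
#' and high-frequency content outside the physiological range.
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Corner frequencies in Hz; `hi` must be below Nyquist.
#' @return Filtered [eeg_recording()].
#' @export
eeg_bandpass <- function(rec, lo = 0.5, hi = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo || hi >= nyq)
    stop("invalid corner frequencies: need 0 < lo < hi < Nyquist (",
         nyq, " Hz)", call. = FALSE)
  filt <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  rec$values <- filtfilt_matrix(filt, rec$values)
  rec
}

#' Power-line notch filter
#'
#' 2nd-order Butterworth band-stop (f0 +/- 1 Hz) applied forward and
#' backward, attenuating the mains component by well over 30 dB while leaving
#' frequencies 5 Hz away essentially untouched.
#'
#' @param rec An [eeg_recording()].
#' @param f0 Line frequency in Hz (default 50).
#' @return Filtered [eeg_recording()].
#' @export
eeg_notch <- function(rec, f0 = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!is.finite(f0) || f0 <= 1 || f0 >= nyq - 1)
    stop("invalid notch frequency: need 1 < f0 < Nyquist - 1", call. = FALSE)
  filt <- signal::butter(2, c(f0 - 1, f0 + 1) / nyq, type = "stop")
  rec$values <- filtfilt_matrix(filt, rec$values)
  rec
}

#' Savitzky-Golay artifact suppression
#'
#' Smooths each channel with a Savitzky-Golay polynomial filter and flags
#' samples whose residual from the smooth trend exceeds `k` robust scale
#' units (median absolute deviation of the residual). Because transients
#' taper below the threshold at their edges, each flagged run is widened by
#' one eighth of the smoothing window on both sides. Flagged samples are
#' replaced by the smoothed value, re-estimated after the first suppression
#' pass so the replacement is not contaminated by the transient itself; all
#' other samples pass through unchanged. This suppresses brief large
#' transients (short blinks, muscle bursts, amplifier saturation steps)
#' while leaving clean oscillatory activity untouched. Transients long
#' relative to the smoothing window are tracked by the polynomial fit and
#' only partially attenuated.
#'
#' @param rec An [eeg_recording()].
#' @param window Smoothing window length in seconds (default 0.511; rounded
#'   to an odd sample count).
#' @param order Polynomial order (default 3); must be below the window length
#'   in samples.
#' @param k Robust-scale multiple for flagging (default 5).
#' @return List with `rec` (cleaned recording) and `mask` (logical matrix,
#'   same shape as the data, `TRUE` where an artifact was replaced).
#' @export
remove_artifacts <- function(rec, window = 0.511, order = 3, k = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- odd_window(window, rec$rate)
  if (n <= order)
    stop("degenerate window: ", n, " samples for polynomial order ", order,
         call. = FALSE)
  if (n >= nrow(rec$values))
    stop("window longer than recording", call. = FALSE)
  mask <- matrix(FALSE, nrow(rec$values), ncol(rec$values),
                 dimnames = dimnames(rec$values))
  margin <- round(n / 8)
  for (ci in seq_len(ncol(rec$values))) {
    x <- rec$values[, ci]
    smooth <- signal::sgolayfilt(x, p = order, n = n)
    resid <- x - smooth
    scale <- mad(resid)
    if (scale <= 0) next
    flag <- abs(resid) > k * scale
    if (!any(flag)) next
    # widen flagged runs over the sub-threshold transient tails
    hits <- which(flag)
    for (i in hits)
      flag[max(1L, i - margin):min(length(x), i + margin)] <- TRUE
    # second pass: re-smooth the suppressed series so the replacement values
    # are free of the transient's own leakage
    x1 <- x
    x1[flag] <- smooth[flag]
    smooth2 <- signal::sgolayfilt(x1, p = order, n = n)
    x[flag] <- smooth2[flag]
    rec$values[, ci] <- x
    mask[, ci] <- flag
  }
  list(rec = rec, mask = mask)
}

#' Decompose an EEG recording into frequency bands
#'
#' Applies the zero-phase 4th-order Butterworth band-pass of [eeg_bandpass()]
#' once per requested band. Requested bands may overlap only in the
#' sanctioned alpha1/alpha2-vs-alpha (and alpha1-vs-theta edge) sense; any
#' other overlapping pair is rejected.
#'
#' @param rec An [eeg_recording()].
#' @param bands Named list of [band_definition()]s (default
#'   [default_bands()]).
#' @return Named list of band-filtered [eeg_recording()]s.
#' @export
band_decompose <- function(rec, bands = default_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_band_overlaps(bands)
  out <- lapply(bands, function(b) eeg_bandpass(rec, b$lo, b$hi))
  names(out) <- vapply(bands, `[[`, "", "name")
  out
}

# Alpha sub-bands may overlap alpha (and alpha1 may brush theta's 7-8 Hz
# edge); all other overlaps indicate a misconfigured band set.
check_band_overlaps <- function(bands) {
  allowed <- function(a, b) {
    ns <- sort(c(a$name, b$name))
    any(vapply(list(c("alpha", "alpha1"), c("alpha", "alpha2"),
                    c("alpha1", "theta"), c("alpha1", "alpha2")),
               function(p) identical(ns, sort(p)), logical(1)))
  }
  bl <- unname(bands)
  if (length(bl) < 2) return(invisible(TRUE))
  for (i in seq_len(length(bl) - 1)) for (j in (i + 1):length(bl)) {
    a <- bl[[i]]; b <- bl[[j]]
    if (max(a$lo, b$lo) < min(a$hi, b$hi) && !allowed(a, b))
      stop("bands '", a$name, "' and '", b$name,
           "' overlap; only alpha/alpha1/alpha2 overlaps are sanctioned",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Baseline-normalize against a resting-state reference
#'
#' Subtracts, per channel, the resting-state mean from the task data. Two
#' modes:
#' * `"literal"` — operates on the raw time series: the resting per-channel
#'   mean amplitude is subtracted from every sample.
#' * `"power"` — operates on windowed band power ([band_power()] objects):
#'   the resting mean log power is subtracted per (channel, band), yielding
#'   log power relative to rest. This is the pipeline default since all
#'   downstream statistics are power-based.
#'
#' @param x An [eeg_recording()] (literal mode) or `power_series` (power
#'   mode).
#' @param reference Resting-state object of the same kind, with an identical
#'   channel set.
#' @param mode `"power"` or `"literal"`; inferred from the class of `x` when
#'   omitted.
#' @return Object of the same kind as `x`. In power mode the returned series
#'   holds log power relative to rest (`log_relative = TRUE`).
#' @export
baseline_normalize <- function(x, reference,
                               mode = c("auto", "power", "literal")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (inherits(x, "power_series")) "power" else "literal"
  if (mode == "literal") {
    stopifnot(inherits(x, "eeg_recording"), inherits(reference, "eeg_recording"))
    missing <- setdiff(x$labels, reference$labels)
    if (length(missing))
      stop("channel(s) missing in reference: ",
           paste(missing, collapse = ", "), call. = FALSE)
    means <- colMeans(reference$values[, x$labels, drop = FALSE], na.rm = TRUE)
    x$values <- sweep(x$values, 2L, means)
    return(x)
  }
  stopifnot(inherits(x, "power_series"), inherits(reference, "power_series"))
  missing <- setdiff(x$channels, reference$channels)
  if (length(missing))
    stop("channel(s) missing in reference: ", paste(missing, collapse = ", "),
         call. = FALSE)
  missing_b <- setdiff(band_names(x), band_names(reference))
  if (length(missing_b))
    stop("band(s) missing in reference: ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  ref_mean <- apply(log(reference$power), c(2, 3), mean, na.rm = TRUE)
  lp <- log(x$power)
  for (ch in x$channels) for (b in band_names(x))
    lp[, ch, b] <- lp[, ch, b] - ref_mean[ch, b]
  x$power <- lp
  x$log_relative <- TRUE
  x
}
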