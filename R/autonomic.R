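#' Convert raw sensor ADC values to conductance
#'
#' Linear calibration `y = p1 * x + p2` mapping the sensor's ADC readout to
#' skin conductance in microsiemens. The coefficients depend on the device's
#' range setting and come from its datasheet; the identity default leaves
#' already-calibrated values untouched.
#'
#' @param x ADC values (numeric vector).
#' @param p1 Gain (muS per ADC unit, non-zero; default 1).
#' @param p2 Offset (muS; default 0).
#' @return Conductance values in muS.
#' @export
adc_to_conductance <- function(x, p1 = 1, p2 = 0) {
  if (!is.finite(p1) || p1 == 0) stop("p1 must be non-zero", call. = FALSE)
  p1 * x + p2
}

#' Low-pass filter an EDA recording
#'
#' 4th-order zero-phase Butterworth low-pass suppressing motion artifacts
#' and other high-frequency noise. The default 1 Hz cutoff — the conservative
#' end of the usable 1-5 Hz range — leaves the slowly varying electrodermal
#' content intact while the 16 Hz stream offers little headroom below its
#' 8 Hz Nyquist.
#'
#' @param rec An [eda_recording()].
#' @param cutoff Cutoff frequency in Hz (default 1), below Nyquist.
#' @return Filtered [eda_recording()].
#' @export
lowpass_eda <- function(rec, cutoff = 1) {
  stopifnot(inherits(rec, "eda_recording"))
  nyq <- rec$rate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must lie in (0, Nyquist = ", nyq, " Hz)", call. = FALSE)
  filt <- signal::butter(4, cutoff / nyq, type = "low")
  x <- as.numeric(rec$values)
  # remove the endpoint-to-endpoint baseline before filtering so the filter
  # startup does not see the tonic level as a step edge, then restore it
  # (the filter is DC-transparent, so this changes nothing in steady state)
  n <- length(x)
  base <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  v <- signal::filtfilt(filt, x - base) + base
  rec$values <- matrix(pmax(v, 0), ncol = 1, dimnames = list(NULL, "eda"))
  rec
}

#' Decompose EDA into tonic and phasic components
#'
#' Splits a (low-passed) skin-conductance signal into a slow tonic baseline
#' and a fast phasic component carrying the skin-conductance responses. The
#' tonic trend is a sliding lower-decile (10th percentile) over an 8 s
#' window: a robust baseline that follows tonic level and drift but is not
#' pulled up by SCR excursions, so phasic peaks retain the full response
#' amplitude. The decomposition is exactly conservative:
#' `tonic + phasic == input`.
#'
#' @param rec An [eda_recording()], ideally after [lowpass_eda()].
#' @param trend_window Baseline window in seconds (default 8).
#' @param trend_quantile Baseline quantile (default 0.1).
#' @return List with `tonic` and `phasic` (numeric vectors), `rec` (the
#'   input) and `times` (seconds).
#' @export
decompose_tonic_phasic <- function(rec, trend_window = 8,
                                   trend_quantile = 0.1) {
  stopifnot(inherits(rec, "eda_recording"))
  x <- as.numeric(rec$values)
  k <- odd_window(trend_window, rec$rate)
  if (k >= length(x))
    stop("recording shorter than the trend window (", trend_window, " s)",
         call. = FALSE)
  tonic <- zoo::rollapply(x, k, quantile, probs = trend_quantile,
                          names = FALSE, fill = NA, align = "center",
                          partial = TRUE)
  tonic <- as.numeric(tonic)
  phasic <- x - tonic
  list(tonic = tonic, phasic = phasic, rec = rec, times = rec_times(rec))
}

#' Detect skin-conductance responses in a phasic signal
#'
#' Scans the phasic component for local-minimum-to-local-maximum excursions:
#' an SCR is an abrupt conductance rise of at least `min_amplitude`
#' completed within `max_rise` seconds. Detections are non-overlapping,
#' time-ordered and separated by at least `refractory` seconds between
#' onsets.
#'
#' @param phasic Phasic conductance vector (muS) or the list returned by
#'   [decompose_tonic_phasic()].
#' @param rate Sampling rate in Hz (default 16; ignored when `phasic` is a
#'   decomposition result).
#' @param min_amplitude Minimum rise amplitude in muS (default 0.05).
#' @param max_rise Maximum onset-to-peak rise time in seconds (default 5).
#' @param refractory Minimum onset separation in seconds (default 1).
#' @return Data frame of SCR events: `onset`, `peak` (seconds), `amplitude`
#'   (muS). Zero rows when nothing crosses threshold.
#' @export
detect_scrs <- function(phasic, rate = 16, min_amplitude = 0.05, max_rise = 5,
                        refractory = 1) {
  if (is.list(phasic)) {
    rate <- phasic$rec$rate
    t0 <- phasic$rec$t0
    phasic <- phasic$phasic
  } else t0 <- 0
  x <- as.numeric(phasic)
  n <- length(x)
  empty <- data.frame(onset = numeric(), peak = numeric(),
                      amplitude = numeric())
  if (n < 3) return(empty)
  d <- diff(x)
  # local minima/maxima via slope sign changes (flat runs collapse to their
  # first sample)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo::na.locf(s, na.rm = FALSE)
  s[is.na(s)] <- 1
  turns <- diff(s)
  minima <- which(turns > 0) + 1L
  maxima <- which(turns < 0) + 1L
  if (!length(minima)) minima <- 1L
  if (length(maxima) && (!length(minima) || maxima[1] < minima[1]))
    minima <- c(1L, minima)

  events <- empty
  last_onset <- -Inf
  for (m in minima) {
    nxt <- maxima[maxima > m]
    if (!length(nxt)) next
    pk <- nxt[1]
    amp <- x[pk] - x[m]
    rise <- (pk - m) / rate
    onset_t <- t0 + (m - 1) / rate
    if (amp >= min_amplitude && rise <= max_rise &&
        onset_t - last_onset >= refractory) {
      events <- rbind(events,
                      data.frame(onset = onset_t,
                                 peak = t0 + (pk - 1) / rate,
                                 amplitude = amp))
      last_onset <- onset_t
    }
  }
  events
}

#' Global SCR index
#'
#' Summarizes detected skin-conductance responses: the index is the mean SCR
#' amplitude in muS (0 when no responses were detected); the count and the
#' rate per minute are reported alongside so a frequency reading of the
#' index remains recoverable.
#'
#' @param events SCR table from [detect_scrs()].
#' @param duration Recording duration in seconds (> 0).
#' @return List with `index` (mean amplitude, muS), `count` and
#'   `rate_per_min`.
#' @export
scr_index <- function(events, duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n <- nrow(events)
  list(index = if (n) mean(events$amplitude) else 0,
       count = n,
       rate_per_min = 60 * n / duration)
}

#' Root mean square of successive differences (RMSSD)
#'
#' Time-domain heart-rate-variability statistic:
#' `sqrt(mean(diff(IBI)^2))` in milliseconds. Low RMSSD accompanies high
#' heart rate — strong concentration, emotion or physical effort; high RMSSD
#' accompanies rest.
#'
#' @param ibi An [ibi_series()] or numeric vector of inter-beat intervals
#'   (ms), at least 2 intervals.
#' @return RMSSD in ms.
#' @export
rmssd <- function(ibi) {
  x <- if (inherits(ibi, "ibi_series")) ibi$ibi_ms else as.numeric(ibi)
  if (length(x) < 2)
    stop("RMSSD needs at least 2 intervals", call. = FALSE)
  sqrt(mean(diff(x)^2))
}

#' Percent change of RMSSD versus rest
#'
#' `100 * (task - rest) / rest`; negative values are decreases relative to
#' the resting state (the typical direction during demanding navigation).
#'
#' @param task_rmssd Task RMSSD (ms).
#' @param rest_rmssd Resting RMSSD (ms), strictly positive.
#' @return Percent change.
#' @export
rmssd_pct_change <- function(task_rmssd, rest_rmssd) {
  if (!is.finite(rest_rmssd) || rest_rmssd <= 0)
    stop("resting RMSSD must be positive", call. = FALSE)
  100 * (task_rmssd - rest_rmssd) / rest_rmssd
}

#' Convert a heart-rate series to inter-beat intervals
#'
#' Maps instantaneous heart rate (beats per minute) to intervals
#' `IBI = 60000 / HR` ms and lays them out on consecutive beat onsets.
#'
#' @param hr Numeric heart-rate samples in bpm, all positive.
#' @param t0 Time of the first beat (seconds, default 0).
#' @return An [ibi_series()].
#' @export
hr_to_ibi <- function(hr, t0 = 0) {
  hr <- as.numeric(hr)
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("heart rate must be positive", call. = FALSE)
  ibi_series(60000 / hr, t0 = t0)
}

#' Autonomic summary of one trial
#'
#' Runs the full electrodermal and heart-rate chain: low-pass, tonic/phasic
#' decomposition, SCR detection and index, RMSSD and (when a resting value
#' is supplied) its percent change versus rest.
#'
#' @param eda An [eda_recording()].
#' @param ibi An [ibi_series()].
#' @param rest_rmssd Optional resting RMSSD (ms).
#' @param ... Tuning arguments forwarded to [detect_scrs()].
#' @return List: `rmssd`, `rmssd_pct_change` (or `NA`), `scr_count`,
#'   `scr_index`, `scr_rate_per_min`, `mean_tonic`, `scrs` (event table).
#' @export
autonomic_summary <- function(eda, ibi, rest_rmssd = NULL, ...) {
  filtered <- lowpass_eda(eda)
  dec <- decompose_tonic_phasic(filtered)
  events <- detect_scrs(dec, ...)
  dur <- rec_duration(eda)
  idx <- scr_index(events, dur)
  task_rmssd <- rmssd(ibi)
  list(rmssd = task_rmssd,
       rmssd_pct_change = if (is.null(rest_rmssd)) NA_real_
                          else rmssd_pct_change(task_rmssd, rest_rmssd),
       scr_count = idx$count, scr_index = idx$index,
       scr_rate_per_min = idx$rate_per_min,
       mean_tonic = mean(dec$tonic), scrs = events)
}
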