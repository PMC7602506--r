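#' Configuration for a synthetic multimodal trial
#'
#' Describes one simulated navigation trial: a 16-channel EEG with per-band
#' oscillation amplitudes and injectable left:right hemispheric power ratios,
#' an electrodermal channel with tonic level/drift and skin-conductance
#' responses, an inter-beat-interval series with controlled jitter, and an
#' event schedule. All downstream analyses can be checked against the ground
#' truth implied by the configuration.
#'
#' Default values model a mid-length indoor navigation trial: a 120 s walk,
#' scalp rhythms at conventional amplitudes (delta 20, theta 10, alpha1 10,
#' alpha2 8, beta 5, gamma 2 muV), 5 muV of 1/f background activity, ~10
#' blinks/min on the prefrontal channels, a 2 muS tonic skin-conductance level
#' with 2 spontaneous SCRs/min, and an 800 ms mean inter-beat interval with
#' 25 ms beat-to-beat jitter.
#'
#' @param duration Trial length in seconds (> 0).
#' @param eeg_rate EEG sampling rate in Hz (default 512).
#' @param eda_rate EDA sampling rate in Hz (default 16).
#' @param channel_labels EEG montage labels (default [default_montage()]).
#' @param band_amplitudes Named numeric vector, synthesis band -> oscillation
#'   amplitude in muV, applied to every channel; or a channels x bands matrix
#'   (rownames = channel labels) for per-channel control. Bands are
#'   delta/theta/alpha1/alpha2/beta/gamma, synthesized as single sinusoids at
#'   2, 6, 9, 11.5, 20 and 38 Hz.
#' @param asym_ratios Named numeric vector, band -> left:right power ratio
#'   injected into every homologous pair (default all 1, i.e. symmetric).
#' @param blink_rate Blink events per minute on Fp1/Fp2 (default 10).
#' @param blink_amplitude Blink peak amplitude in muV (default 200).
#' @param blink_width Blink raised-cosine width in seconds (default 0.4).
#' @param scr_times Onset times (s) of injected skin-conductance responses.
#' @param scr_amplitudes Peak amplitudes (muS) of injected SCRs, recycled to
#'   `length(scr_times)`.
#' @param spontaneous_scr_rate Poisson rate of spontaneous SCRs per minute
#'   (default 2).
#' @param tonic_level Tonic skin-conductance level in muS (default 2).
#' @param tonic_drift Tonic drift in muS per minute (default 0.02).
#' @param eda_noise_sd High-frequency motion-noise SD in muS (default 0.005).
#' @param mean_ibi Mean inter-beat interval in ms (default 800).
#' @param ibi_jitter_sd Beat-to-beat jitter SD in ms (default 25).
#' @param ibi_mode `"random"` (Gaussian jitter) or `"alternating"`
#'   (deterministic `mean + d, mean - d, ...` test mode with `d =
#'   ibi_jitter_sd`, whose RMSSD is exactly `2 d`).
#' @param event_schedule Data frame with columns `event`, `time` (seconds
#'   relative to trial start). Must include one Start and one Stop; default is
#'   `Start` at 0, one `Collision` mid-trial, `Stop` at `duration`.
#' @param noise_sd RMS amplitude of the 1/f EEG background per channel, muV
#'   (default 5).
#' @param start_epoch Unix epoch second of trial start (anchors all
#'   timestamps; default 1700000000).
#' @param seed Integer seed; identical configurations with identical seeds
#'   produce bit-identical trials.
#' @return A validated `trial_config` object.
#' @export
trial_config <- function(duration = 120,
                         eeg_rate = 512,
                         eda_rate = 16,
                         channel_labels = default_montage(),
                         band_amplitudes = c(delta = 20, theta = 10,
                                             alpha1 = 10, alpha2 = 8,
                                             beta = 5, gamma = 2),
                         asym_ratios = NULL,
                         blink_rate = 10,
                         blink_amplitude = 200,
                         blink_width = 0.4,
                         scr_times = numeric(),
                         scr_amplitudes = numeric(),
                         spontaneous_scr_rate = 2,
                         tonic_level = 2,
                         tonic_drift = 0.02,
                         eda_noise_sd = 0.005,
                         mean_ibi = 800,
                         ibi_jitter_sd = 25,
                         ibi_mode = c("random", "alternating"),
                         event_schedule = NULL,
                         noise_sd = 5,
                         start_epoch = 1700000000,
                         seed = 1L) {
  ibi_mode <- match.arg(ibi_mode)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (eeg_rate <= 0 || eda_rate <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  if (mean_ibi <= 0) stop("mean_ibi must be positive", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels", call. = FALSE)

  centers <- synthesis_band_centers()
  amp <- expand_band_amplitudes(band_amplitudes, channel_labels, names(centers))
  if (any(amp < 0)) stop("band amplitudes must be non-negative", call. = FALSE)
  bad <- names(centers)[centers >= eeg_rate / 2]
  if (length(bad))
    stop("synthesis band(s) at/above Nyquist: ", paste(bad, collapse = ", "),
         call. = FALSE)

  ratios <- stats::setNames(rep(1, length(centers)), names(centers))
  if (!is.null(asym_ratios)) {
    unknown <- setdiff(names(asym_ratios), names(centers))
    if (length(unknown))
      stop("unknown band(s) in asym_ratios: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(asym_ratios <= 0))
      stop("asym_ratios must be positive", call. = FALSE)
    ratios[names(asym_ratios)] <- asym_ratios
  }

  if (length(scr_times)) {
    if (any(scr_times < 0 | scr_times >= duration))
      stop("scr_times must lie within [0, duration)", call. = FALSE)
    if (!length(scr_amplitudes)) scr_amplitudes <- 0.2
    scr_amplitudes <- rep_len(scr_amplitudes, length(scr_times))
    if (any(scr_amplitudes < 0))
      stop("scr_amplitudes must be non-negative", call. = FALSE)
  }
  if (tonic_level < 0) stop("tonic level must be non-negative", call. = FALSE)

  if (is.null(event_schedule)) {
    event_schedule <- data.frame(
      event = c("Start", "Collision", "Stop"),
      time = c(0, duration / 2, duration))
  }
  if (!all(c("event", "time") %in% names(event_schedule)))
    stop("event_schedule needs columns event, time", call. = FALSE)

  structure(list(duration = duration, eeg_rate = eeg_rate,
                 eda_rate = eda_rate, channel_labels = channel_labels,
                 band_amplitudes = amp, asym_ratios = ratios,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_width = blink_width,
                 scr_times = as.numeric(scr_times),
                 scr_amplitudes = as.numeric(scr_amplitudes),
                 spontaneous_scr_rate = spontaneous_scr_rate,
                 tonic_level = tonic_level, tonic_drift = tonic_drift,
                 eda_noise_sd = eda_noise_sd, mean_ibi = mean_ibi,
                 ibi_jitter_sd = ibi_jitter_sd, ibi_mode = ibi_mode,
                 event_schedule = event_schedule, noise_sd = noise_sd,
                 start_epoch = start_epoch, seed = as.integer(seed)),
            class = "trial_config")
}

# Accept a named band vector (shared by all channels) or a full channel x band
# matrix; always return the matrix form.
expand_band_amplitudes <- function(x, channels, bands) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("amplitude matrix needs channel rownames and band colnames",
           call. = FALSE)
    unknown <- setdiff(rownames(x), channels)
    if (length(unknown))
      stop("unknown channel label(s) in band_amplitudes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    amp <- matrix(0, length(channels), length(bands),
                  dimnames = list(channels, bands))
    amp[rownames(x), colnames(x)] <- x
    return(amp)
  }
  unknown <- setdiff(names(x), bands)
  if (length(unknown))
    stop("unknown band(s) in band_amplitudes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  amp <- matrix(0, length(channels), length(bands),
                dimnames = list(channels, bands))
  amp[, names(x)] <- matrix(x, length(channels), length(x), byrow = TRUE)
  amp
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("<trial_config: %.0f s, %d EEG ch @ %g Hz, EDA @ %g Hz, seed %d>\n",
              x$duration, length(x$channel_labels), x$eeg_rate, x$eda_rate,
              x$seed))
  invisible(x)
}

# 1/f (pink) background via spectral shaping of white noise, normalized to
# unit RMS then scaled.
pink_noise <- function(n, rms) {
  if (rms == 0) return(numeric(n))
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid the DC singularity
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

#' Generate a synthetic EEG recording
#'
#' Each channel is a sum of one sinusoid per band (delta 2, theta 6, alpha1 9,
#' alpha2 11.5, beta 20, gamma 38 Hz) at the configured amplitude, plus 1/f
#' background noise and raised-cosine blink transients on Fp1/Fp2. Injected
#' left:right power ratios are realized by scaling the left channel of every
#' homologous pair by `sqrt(2 r / (1 + r))` and the right by
#' `sqrt(2 / (1 + r))`, which preserves the pair's mean power while fixing the
#' expected power ratio at `r`.
#'
#' @param config A [trial_config()].
#' @return An [eeg_recording()] anchored at `config$start_epoch`.
#' @export
generate_eeg <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  fs <- config$eeg_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  chans <- config$channel_labels
  centers <- synthesis_band_centers()
  amp <- config$band_amplitudes

  # apply asymmetry ratios to homologous pairs present in the montage
  pairs <- homologous_pairs()
  for (b in names(centers)) {
    r <- config$asym_ratios[[b]]
    if (r == 1) next
    for (left in names(pairs)) {
      right <- pairs[[left]]
      if (left %in% chans && right %in% chans) {
        amp[left, b] <- amp[left, b] * sqrt(2 * r / (1 + r))
        amp[right, b] <- amp[right, b] * sqrt(2 / (1 + r))
      }
    }
  }

  phases <- with_seed(substream_seed(config$seed, "eeg_phase"), {
    matrix(runif(length(chans) * length(centers), 0, 2 * pi),
           length(chans), length(centers), dimnames = list(chans, names(centers)))
  })

  values <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (ci in seq_along(chans)) {
    x <- numeric(n)
    for (bi in seq_along(centers)) {
      a <- amp[ci, bi]
      if (a > 0) x <- x + a * sin(2 * pi * centers[[bi]] * t + phases[ci, bi])
    }
    values[, ci] <- x
  }

  if (config$noise_sd > 0) {
    noise <- with_seed(substream_seed(config$seed, "eeg_noise"), {
      vapply(seq_along(chans), function(i) pink_noise(n, config$noise_sd),
             numeric(n))
    })
    values <- values + noise
  }

  if (config$blink_rate > 0 && config$blink_amplitude > 0) {
    frontal <- intersect(c("Fp1", "Fp2"), chans)
    if (length(frontal)) {
      blink_times <- with_seed(substream_seed(config$seed, "blinks"), {
        k <- rpois(1, config$blink_rate * config$duration / 60)
        sort(runif(k, 0, config$duration - config$blink_width))
      })
      w <- config$blink_width
      for (bt in blink_times) {
        idx <- which(t >= bt & t < bt + w)
        pulse <- config$blink_amplitude *
          0.5 * (1 - cos(2 * pi * (t[idx] - bt) / w))
        for (ch in frontal) values[idx, ch] <- values[idx, ch] + pulse
      }
    }
  }

  eeg_recording(values, rate = fs, labels = chans, t0 = config$start_epoch)
}

# Bi-exponential SCR kernel, normalized to unit peak.
# Shape: exp(-t/tau_decay) - exp(-t/tau_rise), tau_rise 0.75 s, tau_decay 4 s.
scr_kernel <- function(t, tau_rise = 0.75, tau_decay = 4) {
  k <- ifelse(t <= 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  tpk <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  k / (exp(-tpk / tau_decay) - exp(-tpk / tau_rise))
}

#' Generate a synthetic EDA recording with ground truth
#'
#' Tonic level plus linear drift, one bi-exponential skin-conductance response
#' (rise ~0.75 s, decay ~4 s, unit-normalized peak) per configured onset,
#' Poisson-scheduled spontaneous SCRs, and optional high-frequency motion
#' noise.
#'
#' @param config A [trial_config()].
#' @return List with elements `eda` (an [eda_recording()]) and `truth` (a list
#'   with `scr_count`, `scr_times`, `scr_amplitudes`, split into injected and
#'   spontaneous).
#' @export
generate_eda <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  fs <- config$eda_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- config$tonic_level + config$tonic_drift * t / 60

  spont <- with_seed(substream_seed(config$seed, "eda_spont"), {
    k <- rpois(1, config$spontaneous_scr_rate * config$duration / 60)
    list(times = sort(runif(k, 0, config$duration * 0.95)),
         amps = runif(k, 0.05, 0.3))
  })

  all_times <- c(config$scr_times, spont$times)
  all_amps <- c(config$scr_amplitudes, spont$amps)
  ord <- order(all_times)
  for (i in seq_along(all_times))
    x <- x + all_amps[i] * scr_kernel(t - all_times[i])

  if (config$eda_noise_sd > 0) {
    x <- x + with_seed(substream_seed(config$seed, "eda_noise"),
                       rnorm(n, 0, config$eda_noise_sd))
    x <- pmax(x, 0)
  }

  truth <- list(
    scr_count = length(all_times),
    scr_times = all_times[ord],
    scr_amplitudes = all_amps[ord],
    injected = list(times = config$scr_times, amps = config$scr_amplitudes),
    spontaneous = list(times = spont$times, amps = spont$amps),
    tonic_level = config$tonic_level, tonic_drift = config$tonic_drift)

  list(eda = eda_recording(x, rate = fs, t0 = config$start_epoch),
       truth = truth)
}

#' Generate a synthetic inter-beat-interval series
#'
#' In `"random"` mode, intervals are `mean_ibi + N(0, ibi_jitter_sd)` so the
#' expected RMSSD is `sqrt(2) * ibi_jitter_sd`. In `"alternating"` test mode
#' the series is deterministic `m + d, m - d, m + d, ...` whose RMSSD is
#' exactly `2 d`.
#'
#' @param config A [trial_config()].
#' @return An [ibi_series()] whose cumulative time spans `config$duration`.
#' @export
generate_ibi <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  m <- config$mean_ibi
  d <- config$ibi_jitter_sd
  n <- ceiling(config$duration * 1000 / m) + 1L
  ibi <- if (config$ibi_mode == "alternating") {
    m + d * rep_len(c(1, -1), n)
  } else {
    with_seed(substream_seed(config$seed, "ibi"), m + rnorm(n, 0, d))
  }
  if (any(ibi <= 0))
    stop("ibi jitter produced a non-positive interval; reduce ibi_jitter_sd",
         call. = FALSE)
  # keep beats whose onsets fall within the trial
  onsets <- cumsum(c(0, ibi[-n])) / 1000
  keep <- onsets < config$duration
  ibi_series(ibi[keep], t0 = config$start_epoch)
}

# analytic ground truth for the IBI generator
analytic_rmssd <- function(config) {
  if (config$ibi_mode == "alternating") 2 * config$ibi_jitter_sd
  else sqrt(2) * config$ibi_jitter_sd
}

#' Generate the event log of a synthetic trial
#'
#' @param config A [trial_config()].
#' @return An [event_log()] with epoch-anchored timestamps.
#' @export
generate_events <- function(config) {
  sched <- config$event_schedule
  event_log(sched$event, config$start_epoch + sched$time)
}

#' Write a complete synthetic trial to disk
#'
#' Produces the on-disk artifacts of one acquisition session: an HDF5 stream
#' container (`streams.h5` with groups `eeg`, `eda`, `hr`), an annotation CSV
#' (`annotations.csv`, header `event,timestamp`, Unix-epoch seconds) and a
#' ground-truth ledger (`ground_truth.json`). The container round-trips
#' through [read_container()].
#'
#' @param config A [trial_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, a list with `paths` (container, annotations, truth) and
#'   `truth` (the full ground-truth list).
#' @export
generate_trial <- function(config, out_dir) {
  stopifnot(inherits(config, "trial_config"))
  events <- generate_events(config)   # validates schedule before any I/O
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  eeg <- generate_eeg(config)
  eda_res <- generate_eda(config)
  ibi <- generate_ibi(config)

  container <- file.path(out_dir, "streams.h5")
  streams <- list(
    timestamped_stream("eeg", eeg$rate, rec_times(eeg), eeg$values,
                       eeg$labels),
    timestamped_stream("eda", eda_res$eda$rate, rec_times(eda_res$eda),
                       eda_res$eda$values, "eda"),
    timestamped_stream("hr", 1000 / config$mean_ibi, ibi$onset_s,
                       matrix(ibi$ibi_ms, ncol = 1), "ibi_ms",
                       regular = FALSE))
  write_container(streams, container)

  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(events, ann_path)

  counts <- table(factor(config$event_schedule$event, levels = event_labels()))
  truth <- list(
    asym_ratios = as.list(config$asym_ratios),
    scr = eda_res$truth,
    rmssd_analytic = analytic_rmssd(config),
    event_counts = as.list(counts),
    seed = config$seed, duration = config$duration)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(paths = list(container = container, annotations = ann_path,
                              truth = truth_path),
                 truth = truth))
}
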