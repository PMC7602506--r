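#' Pipeline configuration
#'
#' Validated configuration for one end-to-end trial analysis. `trial` is
#' either a [trial_config()] (the trial is simulated, then read back through
#' the container I/O so every run exercises the full chain) or a directory
#' already containing `streams.h5` and `annotations.csv`. Unknown arguments
#' are rejected.
#'
#' @param trial A [trial_config()] or a trial directory path.
#' @param resting Resting-state reference: a [trial_config()], a directory,
#'   or `NULL` to derive a default eyes-open resting configuration
#'   (`resting_duration` seconds, symmetric ratios, no navigation events)
#'   from the trial configuration.
#' @param codification,scenario Behavioral condition labels (see
#'   [trial_record()]).
#' @param bands Analysis bands (default [default_bands()]).
#' @param window,overlap Power-estimation window (s) and fractional overlap.
#' @param cl_band Band driving the cognitive-load index (default `"alpha"`).
#' @param scr_min_amplitude SCR detection threshold in muS (default 0.05).
#' @param valence_neutral,valence_low Valence label thresholds (see
#'   [classify_valence()]).
#' @param baseline_mode `"power"` (default) or `"literal"` baseline
#'   normalization (see [baseline_normalize()]).
#' @param reference_duration Video/timeline length in seconds; defaults to
#'   the trial duration (simulated) or the annotated `Stop - Start` span.
#' @param resting_duration Resting recording length in seconds used when
#'   `resting` is `NULL` (default 60).
#' @param out_dir Output directory; a temporary directory when `NULL`.
#' @param seed Integer seed controlling every stochastic component.
#' @param ... Unknown keys — always an error.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(trial,
                            resting = NULL,
                            codification = "cane",
                            scenario = "A",
                            bands = default_bands(),
                            window = 2,
                            overlap = 0.5,
                            cl_band = "alpha",
                            scr_min_amplitude = 0.05,
                            valence_neutral = 0.05,
                            valence_low = 0.25,
                            baseline_mode = c("power", "literal"),
                            reference_duration = NULL,
                            resting_duration = 60,
                            out_dir = NULL,
                            seed = 1L,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  baseline_mode <- match.arg(baseline_mode)
  if (!(inherits(trial, "trial_config") ||
        (is.character(trial) && length(trial) == 1L)))
    stop("trial must be a trial_config or a directory path", call. = FALSE)
  if (window <= 0 || overlap < 0 || overlap >= 1)
    stop("invalid window/overlap", call. = FALSE)
  structure(list(trial = trial, resting = resting,
                 codification = codification, scenario = scenario,
                 bands = bands, window = window, overlap = overlap,
                 cl_band = cl_band, scr_min_amplitude = scr_min_amplitude,
                 valence_neutral = valence_neutral,
                 valence_low = valence_low, baseline_mode = baseline_mode,
                 reference_duration = reference_duration,
                 resting_duration = resting_duration,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# 32-bit FNV-1a over a character payload, for config provenance hashes.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply in 16-bit halves (doubles stay exact)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL        # scratch location: not part of the analysis
  plain <- rapply(config, function(x) {
    if (inherits(x, "trial_config") || inherits(x, "band_definition"))
      unclass(x) else x
  }, how = "replace")
  fnv1a32(as.character(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                        digits = NA, force = TRUE)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

# Resting reference derived from a trial configuration: same montage, rates,
# rhythm amplitudes and autonomic baseline, symmetric hemispheres, no
# navigation events, no injected SCRs.
derive_resting_config <- function(tc, resting_duration, seed_offset = 104729L) {
  trial_config(
    duration = resting_duration,
    eeg_rate = tc$eeg_rate, eda_rate = tc$eda_rate,
    channel_labels = tc$channel_labels,
    band_amplitudes = tc$band_amplitudes,
    blink_rate = tc$blink_rate, blink_amplitude = tc$blink_amplitude,
    blink_width = tc$blink_width,
    spontaneous_scr_rate = tc$spontaneous_scr_rate,
    tonic_level = tc$tonic_level, tonic_drift = tc$tonic_drift,
    eda_noise_sd = tc$eda_noise_sd,
    mean_ibi = tc$mean_ibi, ibi_jitter_sd = tc$ibi_jitter_sd,
    event_schedule = data.frame(event = c("Start", "Stop"),
                                time = c(0, resting_duration)),
    noise_sd = tc$noise_sd, start_epoch = tc$start_epoch,
    seed = (tc$seed + seed_offset) %% .Machine$integer.max)
}

# Simulate (if needed) then ingest one trial directory; returns recordings on
# the trial-relative timebase plus the event log.
ingest_trial <- function(source, dir_hint, reference_duration = NULL) {
  dir <- source
  if (inherits(source, "trial_config")) {
    dir <- dir_hint
    generate_trial(source, dir)
  }
  container <- file.path(dir, "streams.h5")
  ann <- file.path(dir, "annotations.csv")
  streams <- read_container(container)
  for (need in c("eeg", "eda", "hr"))
    if (!need %in% names(streams))
      stop("missing stream '", need, "'", call. = FALSE)
  events <- read_annotations(ann)
  ref <- reference_duration %||% (log_stop(events) - log_start(events))
  # the beat stream is irregular: count-based trimming/padding does not apply
  aligned <- align_streams(streams[c("eeg", "eda")], ref)
  sliced <- lapply(aligned$streams[c("eeg", "eda")], slice_by_events, events)
  hr <- streams$hr
  keep <- hr$timestamps >= log_start(events) & hr$timestamps < log_stop(events)
  list(eeg = stream_to_recording(sliced$eeg$stream),
       eda = stream_to_recording(sliced$eda$stream),
       ibi = ibi_series(as.numeric(hr$values[keep, 1]),
                        onset_s = hr$timestamps[keep] - log_start(events)),
       events = sliced$eeg$events,
       alignment = aligned$report)
}

preprocess_eeg <- function(eeg, bands, window, overlap) {
  eeg <- eeg_bandpass(eeg)
  eeg <- eeg_notch(eeg)
  cleaned <- remove_artifacts(eeg)
  power <- band_power(cleaned$rec, bands, window = window, overlap = overlap)
  list(rec = cleaned$rec, mask = cleaned$mask, power = power)
}

#' Run the full trial analysis pipeline
#'
#' simulate (optional) -> ingest -> align/slice -> EEG conditioning ->
#' band power -> cognitive load, asymmetry envelopes, visual-cortex
#' asymmetry -> valence -> autonomic indices -> behavioral metrics, with a
#' provenance-stamped report. Deterministic for a fixed (config, seed):
#' two runs write byte-identical report payloads.
#'
#' @param config A [pipeline_config()].
#' @return A `trial_report` list; the JSON payload and metric CSVs are
#'   persisted under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir %||% tempfile("navload-run-")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ing <- stage("ingest", ingest_trial(config$trial,
                                      file.path(out_dir, "trial"),
                                      config$reference_duration))

  resting_src <- config$resting
  if (is.null(resting_src)) {
    if (!inherits(config$trial, "trial_config"))
      stop("stage 'resting': no resting reference configured for an ",
           "on-disk trial", call. = FALSE)
    resting_src <- derive_resting_config(config$trial,
                                         config$resting_duration)
  }
  rest <- stage("resting", ingest_trial(resting_src,
                                        file.path(out_dir, "resting")))

  task <- stage("eeg", preprocess_eeg(ing$eeg, config$bands, config$window,
                                      config$overlap))
  rest_eeg <- stage("eeg", preprocess_eeg(rest$eeg, config$bands,
                                          config$window, config$overlap))

  cl <- stage("cognitive_load", {
    frontal <- lapply(list(c("F3", "F4"), c("Fp1", "Fp2")), function(p) {
      if (!all(p %in% task$power$channels)) return(NULL)
      cl_index(asymmetry_series(task$power, p[1], p[2],
                                band = config$cl_band))
    })
    names(frontal) <- c("F3-F4", "Fp1-Fp2")
    frontal <- Filter(Negate(is.null), frontal)
    env <- lapply(c(alpha1 = "alpha1", alpha2 = "alpha2"), function(b) {
      if (!b %in% band_names(task$power)) return(NULL)
      asymmetry_envelope(asymmetry_series(task$power, "F3", "F4", band = b),
                         ing$events)
    })
    list(series = frontal,
         envelopes = Filter(Negate(is.null), env),
         global = global_cl(task$power, rest_eeg$power),
         vc = vc_asymmetry(task$power, rest_eeg$power))
  })

  val <- stage("valence", {
    vs <- valence_over_time(task$power)
    list(series = vs,
         table = valence_table(vs, neutral = config$valence_neutral,
                               low = config$valence_low))
  })

  aut <- stage("autonomic", {
    rest_rmssd <- rmssd(rest$ibi)
    autonomic_summary(ing$eda, ing$ibi, rest_rmssd = rest_rmssd,
                      min_amplitude = config$scr_min_amplitude)
  })

  beh <- stage("behavior", {
    trial_metrics(trial_record(config$codification, config$scenario,
                               ing$events))
  })

  mean_valid <- function(x) mean(x[is.finite(x)])
  report <- structure(list(
    cl = cl, valence = val, autonomic = aut, behavior = beh,
    alignment = ing$alignment,
    summary = list(
      cl_mean = lapply(cl$series, function(s) mean_valid(s$cl)),
      cl_global_median = cl$global$summary$median,
      vc_ln_ratio = cl$vc$ln_ratio_mean,
      vc_tcl = as.list(cl$vc$tcl),
      valence_aggregate = stats::setNames(as.list(val$table$aggregate),
                                          val$table$pair),
      rmssd = aut$rmssd, rmssd_pct_change = aut$rmssd_pct_change,
      scr_index = aut$scr_index, scr_count = aut$scr_count),
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("navload"))),
    out_dir = out_dir),
    class = "trial_report")

  payload <- list(summary = report$summary, behavior = beh,
                  valence_table = val$table,
                  cl_distribution = cl$global$summary,
                  provenance = report$provenance)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  report
}

#' @export
print.trial_report <- function(x, ...) {
  s <- x$summary
  cat("<trial_report>\n")
  cat(sprintf("  global CL median: %.4f; VC ln-ratio: %.4f\n",
              s$cl_global_median, s$vc_ln_ratio))
  cat(sprintf("  RMSSD %.1f ms (%+.1f%% vs rest); SCR index %.3f (n=%d)\n",
              s$rmssd, s$rmssd_pct_change, s$scr_index, s$scr_count))
  cat(sprintf("  behavior: %s/%s, %d collisions, %.0f s\n",
              x$behavior$codification, x$behavior$scenario,
              x$behavior$collisions, x$behavior$duration_s))
  invisible(x)
}

#' Compare trial reports across conditions
#'
#' Descriptive (non-inferential) comparison of groups of trial reports:
#' per-group median, quartiles, IQR, 1.5 IQR whisker bounds and skewness of
#' the trial-level cognitive-load means, plus group means of the global CL
#' median, temporal-pair valence, SCR index and RMSSD change.
#'
#' @param groups Named list (>= 2 entries), each a list of `trial_report`s.
#' @param cl_pair Which frontal CL series to compare (default `"F3-F4"`).
#' @return Data frame, one row per group.
#' @export
compare_conditions <- function(groups, cl_pair = "F3-F4") {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  rows <- lapply(names(groups), function(g) {
    reps <- groups[[g]]
    if (!length(reps)) stop("group '", g, "' has zero trials", call. = FALSE)
    cl_means <- vapply(reps, function(r) {
      v <- r$summary$cl_mean[[cl_pair]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    ds <- distribution_summary(cl_means)
    data.frame(
      group = g, n_trials = length(reps),
      cl_median = ds$median, cl_q1 = ds$q1, cl_q3 = ds$q3, cl_iqr = ds$iqr,
      cl_whisker_lo = ds$whisker_lo, cl_whisker_hi = ds$whisker_hi,
      cl_skewness = ds$skewness,
      global_cl_median = mean(vapply(reps, function(r)
        r$summary$cl_global_median, numeric(1))),
      valence_t8_t7 = mean(vapply(reps, function(r)
        r$summary$valence_aggregate[["T8-T7"]] %||% NA_real_, numeric(1))),
      scr_index = mean(vapply(reps, function(r)
        r$summary$scr_index, numeric(1))),
      rmssd_pct_change = mean(vapply(reps, function(r)
        r$summary$rmssd_pct_change, numeric(1))),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
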