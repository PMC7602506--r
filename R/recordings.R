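#' EEG recording container
#'
#' A regularly sampled multi-channel EEG segment. Values are stored
#' samples x channels in microvolts; `t0` anchors the first sample on the
#' trial timeline (epoch seconds or trial-relative seconds).
#'
#' @param values Numeric matrix, samples x channels (muV).
#' @param rate Sampling rate in Hz (512 for the supported amplifier).
#' @param labels Channel labels (10-20 names), unique, one per column.
#' @param t0 Time of the first sample in seconds (default 0).
#' @param reference Reference electrode description (default `"ear"`).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(values, rate = 512, labels = default_montage(),
                          t0 = 0, reference = "ear") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("EEG values must be numeric", call. = FALSE)
  if (length(labels) != ncol(values))
    stop("labels length (", length(labels), ") != channel count (",
         ncol(values), ")", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  colnames(values) <- labels
  structure(list(values = values, rate = rate, labels = labels,
                 t0 = t0, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d ch x %d samples @ %g Hz (%.1f s), ref %s>\n",
              ncol(x$values), nrow(x$values), x$rate,
              nrow(x$values) / x$rate, x$reference))
  invisible(x)
}

# seconds timeline of an eeg/eda recording
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$values)) - 1L) / rec$rate

rec_duration <- function(rec) nrow(rec$values) / rec$rate

#' Electrodermal activity recording
#'
#' Single-channel skin-conductance series in microsiemens, regularly sampled
#' (16 Hz for the supported Bluetooth sensor stream).
#'
#' @param values Numeric vector of conductance samples (muS).
#' @param rate Sampling rate in Hz (default 16).
#' @param t0 Time of first sample in seconds (default 0).
#' @return An `eda_recording` object.
#' @export
eda_recording <- function(values, rate = 16, t0 = 0) {
  values <- as.numeric(values)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("conductance values must be non-negative (muS)", call. = FALSE)
  structure(list(values = matrix(values, ncol = 1,
                                 dimnames = list(NULL, "eda")),
                 rate = rate, t0 = t0),
            class = "eda_recording")
}

#' @export
print.eda_recording <- function(x, ...) {
  cat(sprintf("<eda_recording: %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$values), x$rate, nrow(x$values) / x$rate))
  invisible(x)
}

#' Inter-beat interval series
#'
#' @param ibi_ms Inter-beat intervals in milliseconds, all positive.
#' @param onset_s Beat onset times in seconds; computed by cumulating the
#'   intervals from `t0` when omitted.
#' @param t0 Time of the first beat (seconds, default 0).
#' @return An `ibi_series` object.
#' @export
ibi_series <- function(ibi_ms, onset_s = NULL, t0 = 0) {
  ibi_ms <- as.numeric(ibi_ms)
  if (any(!is.finite(ibi_ms)) || any(ibi_ms <= 0))
    stop("all inter-beat intervals must be positive and finite", call. = FALSE)
  if (is.null(onset_s)) onset_s <- t0 + cumsum(c(0, ibi_ms[-length(ibi_ms)])) / 1000
  if (length(onset_s) != length(ibi_ms))
    stop("onset_s and ibi_ms lengths differ", call. = FALSE)
  structure(list(ibi_ms = ibi_ms, onset_s = onset_s), class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series: %d beats, mean IBI %.0f ms>\n",
              length(x$ibi_ms), mean(x$ibi_ms)))
  invisible(x)
}

#' Known navigation event labels
#' @return Character vector of the six supported annotation labels.
#' @export
event_labels <- function() {
  c("Start", "Collision", "Find", "Lost", "TouchCane", "Stop")
}

#' Navigation event log
#'
#' Validated table of annotated navigation events. Exactly one `Start` and one
#' `Stop` are required, timestamps must be non-decreasing and every event must
#' lie within `[Start, Stop]`.
#'
#' @param events Character vector of labels (see [event_labels()]).
#' @param timestamps Numeric timestamps in seconds (Unix epoch or
#'   trial-relative), same length as `events`.
#' @return An `event_log` object (a data.frame with columns `event`,
#'   `timestamp`).
#' @export
event_log <- function(events, timestamps) {
  events <- as.character(events)
  timestamps <- as.numeric(timestamps)
  if (length(events) != length(timestamps))
    stop("events and timestamps lengths differ", call. = FALSE)
  unknown <- setdiff(unique(events), event_labels())
  if (length(unknown))
    stop("unknown event label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (sum(events == "Start") != 1L)
    stop("event log must contain exactly one Start", call. = FALSE)
  if (sum(events == "Stop") != 1L)
    stop("event log must contain exactly one Stop", call. = FALSE)
  if (is.unsorted(timestamps))
    stop("event timestamps must be non-decreasing", call. = FALSE)
  t_start <- timestamps[events == "Start"]
  t_stop <- timestamps[events == "Stop"]
  if (t_stop < t_start)
    stop("Stop precedes Start", call. = FALSE)
  if (any(timestamps < t_start) || any(timestamps > t_stop))
    stop("all events must lie within [Start, Stop]", call. = FALSE)
  structure(data.frame(event = events, timestamp = timestamps,
                       stringsAsFactors = FALSE),
            class = c("event_log", "data.frame"))
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log: %d events over %.1f s>\n", nrow(x),
              diff(range(x$timestamp))))
  print.data.frame(x, ...)
  invisible(x)
}

# Start/Stop accessors
log_start <- function(log) log$timestamp[log$event == "Start"]
log_stop <- function(log) log$timestamp[log$event == "Stop"]
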