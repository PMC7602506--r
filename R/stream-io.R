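#' Timestamped data stream
#'
#' One acquisition stream: a samples x channels value matrix with one
#' timestamp per sample and a nominal sampling rate. Timestamps must be
#' monotone non-decreasing and, for regularly sampled streams, their median
#' spacing must agree with the nominal rate within 1%.
#'
#' @param name Stream name (e.g. `"eeg"`, `"eda"`, `"hr"`).
#' @param nominal_rate Nominal rate in Hz.
#' @param timestamps Seconds (epoch-anchored), length = sample count.
#' @param values Samples x channels numeric matrix.
#' @param labels Channel labels, one per column.
#' @param regular Whether the stream is regularly sampled (default `TRUE`).
#'   Beat-event streams such as `hr` are irregular by nature; the rate/spacing
#'   consistency check only applies to regular streams.
#' @return A `timestamped_stream` object.
#' @export
timestamped_stream <- function(name, nominal_rate, timestamps, values,
                               labels, regular = TRUE) {
  values <- as.matrix(values)
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nrow(values))
    stop("stream '", name, "': timestamps length != sample count",
         call. = FALSE)
  if (is.unsorted(timestamps))
    stop("stream '", name, "': timestamps must be monotone non-decreasing",
         call. = FALSE)
  if (length(labels) != ncol(values))
    stop("stream '", name, "': labels length != channel count", call. = FALSE)
  if (nominal_rate <= 0)
    stop("stream '", name, "': nominal rate must be positive", call. = FALSE)
  if (isTRUE(regular) && length(timestamps) > 16L) {
    spacing <- median(diff(timestamps))
    if (spacing > 0 && abs(spacing - 1 / nominal_rate) > 0.01 / nominal_rate)
      stop("stream '", name, "': median timestamp spacing ",
           signif(spacing, 4), " s inconsistent with nominal rate ",
           nominal_rate, " Hz", call. = FALSE)
  }
  colnames(values) <- labels
  structure(list(name = name, nominal_rate = nominal_rate,
                 timestamps = timestamps, values = values,
                 labels = as.character(labels), regular = isTRUE(regular)),
            class = "timestamped_stream")
}

#' @export
print.timestamped_stream <- function(x, ...) {
  cat(sprintf("<stream '%s': %d ch x %d samples @ %g Hz>\n", x$name,
              ncol(x$values), nrow(x$values), x$nominal_rate))
  invisible(x)
}

stream_duration <- function(s) nrow(s$values) / s$nominal_rate

#' Write streams to an HDF5 container
#'
#' Layout: one group per stream holding datasets `time` (seconds, double) and
#' `values` (samples x channels, double), with group attributes `rate_hz` and
#' `labels`.
#'
#' @param streams List of [timestamped_stream()] objects.
#' @param path Output `.h5` file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_container <- function(streams, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (s in streams) {
    stopifnot(inherits(s, "timestamped_stream"))
    rhdf5::h5createGroup(path, s$name)
    rhdf5::h5write(s$timestamps, path, paste0(s$name, "/time"))
    rhdf5::h5write(unname(s$values), path, paste0(s$name, "/values"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, s$name)
    rhdf5::h5writeAttribute(s$nominal_rate, gid, "rate_hz")
    rhdf5::h5writeAttribute(s$labels, gid, "labels")
    rhdf5::h5writeAttribute(as.integer(s$regular), gid, "regular")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read an HDF5 stream container
#'
#' Reads every group of the container written by [write_container()] (or any
#' file following the same layout) and validates the stream invariants:
#' presence of `time`/`values` datasets and the `rate_hz`/`labels` attributes,
#' monotone timestamps, and rate/spacing consistency.
#'
#' @param path Container file path.
#' @return Named list of [timestamped_stream()] objects.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  index <- rhdf5::h5ls(path)
  groups <- index$name[index$group == "/" & index$otype == "H5I_GROUP"]
  if (!length(groups)) stop("container has no stream groups", call. = FALSE)
  streams <- list()
  for (g in groups) {
    members <- index$name[index$group == paste0("/", g)]
    for (need in c("time", "values"))
      if (!need %in% members)
        stop("group '", g, "': missing dataset '", need, "'", call. = FALSE)
    attrs <- rhdf5::h5readAttributes(path, g)
    if (is.null(attrs$rate_hz))
      stop("group '", g, "': missing attribute 'rate_hz'", call. = FALSE)
    if (is.null(attrs$labels))
      stop("group '", g, "': missing attribute 'labels'", call. = FALSE)
    time <- as.numeric(rhdf5::h5read(path, paste0(g, "/time")))
    values <- rhdf5::h5read(path, paste0(g, "/values"))
    if (is.null(dim(values))) values <- matrix(values, ncol = 1)
    regular <- if (is.null(attrs$regular)) TRUE else as.logical(attrs$regular)
    streams[[g]] <- timestamped_stream(g, as.numeric(attrs$rate_hz), time,
                                       values, as.character(attrs$labels),
                                       regular = regular)
  }
  streams
}

#' Read an annotation CSV into an event log
#'
#' Expects the two-column dialect `event,timestamp` with Unix-epoch seconds
#' (dot decimal). Labels and Start/Stop structure are validated by
#' [event_log()].
#'
#' @param path CSV file path.
#' @return An [event_log()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event", "timestamp") %in% names(df)))
    stop("annotation CSV must have columns event,timestamp", call. = FALSE)
  event_log(df$event, df$timestamp)
}

#' Write an event log as an annotation CSV
#'
#' @param log An [event_log()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align streams to a reference timeline
#'
#' Trims or pads every stream so that it spans exactly `reference_duration`
#' seconds (within one sample at its nominal rate), the way recordings are
#' fitted to the movie length of the trial video. Overruns are trimmed at the
#' tail; shortfalls are padded with `NA` missing-value markers, which
#' propagate (they are never imputed here) and cause downstream power windows
#' with more than 10% missing samples to be dropped.
#'
#' @param streams List of [timestamped_stream()] objects.
#' @param reference_duration Reference (video) length in seconds.
#' @return List with `streams` (aligned) and `report` (data frame with one
#'   row per stream: seconds trimmed, seconds padded, residual offset,
#'   misalignment flag).
#' @export
align_streams <- function(streams, reference_duration) {
  if (!is.finite(reference_duration) || reference_duration <= 0)
    stop("reference_duration must be positive", call. = FALSE)
  if (inherits(streams, "timestamped_stream")) streams <- list(streams)
  aligned <- list()
  rows <- list()
  for (s in streams) {
    dur <- stream_duration(s)
    if (dur < 0.5 * reference_duration)
      stop("stream '", s$name, "' overlaps the reference by ",
           round(100 * dur / reference_duration), "% (< 50%): gross clock error",
           call. = FALSE)
    n_target <- round(reference_duration * s$nominal_rate)
    n <- nrow(s$values)
    trimmed <- padded <- 0
    if (n > n_target) {
      trimmed <- (n - n_target) / s$nominal_rate
      s$values <- s$values[seq_len(n_target), , drop = FALSE]
      s$timestamps <- s$timestamps[seq_len(n_target)]
    } else if (n < n_target) {
      padded <- (n_target - n) / s$nominal_rate
      pad <- matrix(NA_real_, n_target - n, ncol(s$values))
      s$values <- rbind(s$values, pad)
      t_last <- if (n > 0) s$timestamps[n] else 0
      s$timestamps <- c(s$timestamps,
                        t_last + seq_len(n_target - n) / s$nominal_rate)
    }
    residual <- nrow(s$values) / s$nominal_rate - reference_duration
    rows[[s$name]] <- data.frame(
      stream = s$name, trimmed_s = trimmed, padded_s = padded,
      residual_offset_s = residual,
      misaligned = abs(residual) > 1 / s$nominal_rate,
      stringsAsFactors = FALSE)
    aligned[[s$name]] <- s
  }
  list(streams = aligned,
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Slice a stream to the [Start, Stop) window of an event log
#'
#' Restricts the stream to the half-open trial window and re-expresses both
#' sample and event times relative to `Start`.
#'
#' @param stream A [timestamped_stream()].
#' @param log An [event_log()] on the same (absolute) timebase.
#' @return List with `stream` (sliced, relative timebase) and `events`
#'   (an [event_log()] with timestamps relative to Start).
#' @export
slice_by_events <- function(stream, log) {
  stopifnot(inherits(stream, "timestamped_stream"), inherits(log, "event_log"))
  t0 <- log_start(log)
  t1 <- log_stop(log)
  keep <- stream$timestamps >= t0 & stream$timestamps < t1
  if (!any(keep))
    stop("empty window: no samples of stream '", stream$name,
         "' fall in [Start, Stop)", call. = FALSE)
  out <- timestamped_stream(stream$name, stream$nominal_rate,
                            stream$timestamps[keep] - t0,
                            stream$values[keep, , drop = FALSE],
                            stream$labels)
  rel <- log
  rel$timestamp <- rel$timestamp - t0
  list(stream = out, events = rel)
}

#' Convert a sliced stream back to a typed recording
#'
#' @param stream A [timestamped_stream()].
#' @return An [eeg_recording()], [eda_recording()] or [ibi_series()] depending
#'   on the stream name (`eeg`, `eda`, `hr`).
#' @export
stream_to_recording <- function(stream) {
  stopifnot(inherits(stream, "timestamped_stream"))
  t0 <- if (length(stream$timestamps)) stream$timestamps[1] else 0
  switch(stream$name,
    eeg = eeg_recording(stream$values, rate = stream$nominal_rate,
                        labels = stream$labels, t0 = t0),
    eda = eda_recording(as.numeric(stream$values), rate = stream$nominal_rate,
                        t0 = t0),
    hr = ibi_series(as.numeric(stream$values), onset_s = stream$timestamps),
    stop("unknown stream kind: ", stream$name, call. = FALSE))
}
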