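#' Navigation trial record
#'
#' Bundles the behavioral description of one trial: the guidance condition
#' (white cane or one of the device encodings), the obstacle-scenario label,
#' the validated event log, and optionally the walked path as timestamped 2-D
#' positions in metres.
#'
#' @param codification One of `"audio"`, `"haptic"`, `"multimodal"`,
#'   `"cane"`.
#' @param scenario Scenario label, one of `"A"`-`"E"`.
#' @param events An [event_log()].
#' @param path Optional data frame with columns `x`, `y` (metres) and
#'   optionally `time` (seconds within `[Start, Stop]`).
#' @return A `trial_record` object.
#' @export
trial_record <- function(codification, scenario, events, path = NULL) {
  codification <- match.arg(codification,
                            c("audio", "haptic", "multimodal", "cane"))
  scenario <- match.arg(scenario, c("A", "B", "C", "D", "E"))
  stopifnot(inherits(events, "event_log"))
  if (!is.null(path)) {
    if (!all(c("x", "y") %in% names(path)))
      stop("path needs columns x, y", call. = FALSE)
    if ("time" %in% names(path)) {
      t0 <- log_start(events); t1 <- log_stop(events)
      if (any(path$time < t0 | path$time > t1))
        stop("path timestamps must lie within [Start, Stop]", call. = FALSE)
    }
  }
  structure(list(codification = codification, scenario = scenario,
                 events = events, path = path),
            class = "trial_record")
}

#' Per-trial navigation metrics
#'
#' Duration is `Stop - Start`; collisions and cane contacts are event
#' counts; path length is the sum of Euclidean distances between consecutive
#' positions. Cane contacts are reported as `NA` (blank) for device
#' conditions, since the count is only meaningful for white-cane trials;
#' path length is `NA` when no path was recorded (it is never silently 0).
#'
#' @param trial A [trial_record()].
#' @return One-row data frame: `codification`, `scenario`, `duration_s`,
#'   `collisions`, `cane_contacts`, `path_length_m`, `finds`, `losts`.
#' @export
trial_metrics <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  ev <- trial$events
  dist <- NA_real_
  if (!is.null(trial$path) && nrow(trial$path) >= 2)
    dist <- sum(sqrt(diff(trial$path$x)^2 + diff(trial$path$y)^2))
  cane <- if (trial$codification == "cane") sum(ev$event == "TouchCane")
          else NA_integer_
  data.frame(codification = trial$codification, scenario = trial$scenario,
             duration_s = log_stop(ev) - log_start(ev),
             collisions = sum(ev$event == "Collision"),
             cane_contacts = cane,
             path_length_m = dist,
             finds = sum(ev$event == "Find"),
             losts = sum(ev$event == "Lost"),
             stringsAsFactors = FALSE)
}

#' Aggregate trial metrics into a cumulative table
#'
#' Cumulative sums per (codification, scenario) cell — collisions, total
#' distance, total time, cane contacts — plus per-scenario averages across
#' trials. Aggregation is a plain sum, so cell totals equal the sum of their
#' constituent trials exactly and are invariant to trial order.
#'
#' @param trials List of [trial_record()]s (or a data frame of
#'   [trial_metrics()] rows).
#' @return A `metrics_table`: list with `cumulative` (per-cell totals),
#'   `scenario_averages` (per codification x scenario trial means) and
#'   `per_trial` (the underlying rows).
#' @export
aggregate_metrics <- function(trials) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  if (is.data.frame(trials)) per_trial <- trials
  else {
    if (!length(trials)) stop("no trials to aggregate", call. = FALSE)
    per_trial <- do.call(rbind, lapply(trials, trial_metrics))
  }
  if (!nrow(per_trial)) stop("no trials to aggregate", call. = FALSE)

  key <- interaction(per_trial$codification, per_trial$scenario, drop = TRUE)
  sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  cum <- do.call(rbind, lapply(split(per_trial, key), function(g) {
    data.frame(codification = g$codification[1], scenario = g$scenario[1],
               trials = nrow(g),
               collisions_total = sum(g$collisions),
               path_total_distance_m = sum_na(g$path_length_m),
               total_time_s = sum(g$duration_s),
               cane_contacts = sum_na(g$cane_contacts),
               stringsAsFactors = FALSE)
  }))
  avg <- do.call(rbind, lapply(split(per_trial, key), function(g) {
    data.frame(codification = g$codification[1], scenario = g$scenario[1],
               mean_time_s = mean(g$duration_s),
               mean_collisions = mean(g$collisions),
               mean_distance_m = if (all(is.na(g$path_length_m))) NA_real_
                                 else mean(g$path_length_m, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  ord <- order(cum$codification, cum$scenario)
  structure(list(cumulative = cum[ord, , drop = FALSE],
                 scenario_averages = avg[ord, , drop = FALSE],
                 per_trial = per_trial),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("<metrics_table> cumulative per (codification, scenario):\n")
  print(x$cumulative, row.names = FALSE)
  invisible(x)
}

#' Export a metrics table as CSV
#'
#' Writes the cumulative table with report-style column headers:
#' Codification, Scenario Type, Collisions Total Number, Path Total
#' Distance (m), Total Time (s), Cane Contacts.
#'
#' @param table A `metrics_table` from [aggregate_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  stopifnot(inherits(table, "metrics_table"))
  df <- table$cumulative
  out <- data.frame(
    `Codification` = df$codification,
    `Scenario Type` = df$scenario,
    `Collisions Total Number` = df$collisions_total,
    `Path Total Distance (m)` = df$path_total_distance_m,
    `Total Time (s)` = df$total_time_s,
    `Cane Contacts` = df$cane_contacts,
    check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
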