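#' Valence state from a right/left power ratio
#'
#' `VS = ln(PS_R / PS_L)`, the log ratio of the right and left hemisphere
#' band power for a homologous channel pair. Left frontal inactivation (a
#' withdrawal response, negative emotion) drives VS negative through the
#' relevant pairs; right inactivation (approach, positive emotion) drives it
#' positive. Unlike the cognitive-load asymmetry index, VS is invariant to a
#' common rescaling of both powers.
#'
#' @param ps_right,ps_left Band power of the right / left channel (muV^2),
#'   strictly positive. Vectorized.
#' @return Numeric valence-state values (dimensionless, natural log).
#' @export
valence_state <- function(ps_right, ps_left) {
  if (any(ps_right <= 0, na.rm = TRUE) || any(ps_left <= 0, na.rm = TRUE))
    stop("powers must be strictly positive", call. = FALSE)
  log(ps_right / ps_left)
}

#' Valence state over time for electrode pairs and bands
#'
#' Computes the windowed valence state for each requested (pair, band)
#' combination, plus the trial-level mean (the mean of the windowed VS
#' values, not the VS of the mean powers).
#'
#' @param power A raw `power_series` from [band_power()].
#' @param pairs List of `c(right, left)` channel pairs (default
#'   [valence_pairs()]).
#' @param bands Band names to evaluate (default alpha, beta, gamma — the
#'   bands carrying affective information).
#' @return List of `valence_series` data frames (`center`, `vs`, `valid`)
#'   with attributes `pair`, `band` and `trial_mean`, named
#'   `"<right>-<left>.<band>"`.
#' @export
valence_over_time <- function(power, pairs = valence_pairs(),
                              bands = c("alpha", "beta", "gamma")) {
  stopifnot(inherits(power, "power_series"))
  if (isTRUE(power$log_relative))
    stop("valence requires raw power, not baseline-normalized log power",
         call. = FALSE)
  missing_b <- setdiff(bands, band_names(power))
  if (length(missing_b))
    stop("band(s) not present: ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (pair in pairs) {
    right <- pair[1]; left <- pair[2]
    for (ch in c(right, left))
      if (!ch %in% power$channels)
        stop("missing channel '", ch, "' for pair ", right, "-", left,
             call. = FALSE)
    for (b in bands) {
      pr <- power$power[, right, b]
      pl <- power$power[, left, b]
      ok <- is.finite(pr) & is.finite(pl) & pr > 0 & pl > 0
      vs <- rep(NA_real_, length(pr))
      vs[ok] <- valence_state(pr[ok], pl[ok])
      key <- paste0(right, "-", left, ".", b)
      out[[key]] <- structure(
        data.frame(center = power$center, vs = vs, valid = ok),
        pair = c(right, left), band = b, trial_mean = mean(vs[ok]),
        class = c("valence_series", "data.frame"))
    }
  }
  out
}

#' Qualitative valence label
#'
#' Maps a mean valence state onto the qualitative scale used in trial
#' reports, with fixed symmetric thresholds: `|VS| < neutral` is neutral,
#' up to `low` is "low positive"/"low negative", beyond that
#' "positive"/"negative".
#'
#' @param mean_vs Trial-level mean valence state (finite scalar or vector).
#' @param neutral Neutral half-width (default 0.05).
#' @param low Low/strong boundary (default 0.25).
#' @return Character label(s) from `neutral`, `low positive`, `low negative`,
#'   `positive`, `negative`.
#' @export
classify_valence <- function(mean_vs, neutral = 0.05, low = 0.25) {
  stopifnot(neutral > 0, low > neutral)
  vapply(mean_vs, function(v) {
    if (!is.finite(v)) return(NA_character_)
    if (abs(v) < neutral) return("neutral")
    side <- if (v > 0) "positive" else "negative"
    if (abs(v) <= low) paste("low", side) else side
  }, character(1))
}

#' Valence report table
#'
#' Arranges trial-mean valence states as a pairs x bands table with a
#' per-pair aggregate (mean over bands) and its qualitative label.
#'
#' @param vs_list Output of [valence_over_time()].
#' @param ... Threshold arguments passed to [classify_valence()].
#' @return Data frame, one row per pair: per-band means, `aggregate`,
#'   `label`.
#' @export
valence_table <- function(vs_list, ...) {
  pairs <- unique(vapply(vs_list, function(s)
    paste(attr(s, "pair"), collapse = "-"), character(1)))
  bands <- unique(vapply(vs_list, attr, "", "band"))
  tab <- matrix(NA_real_, length(pairs), length(bands),
                dimnames = list(pairs, bands))
  for (s in vs_list)
    tab[paste(attr(s, "pair"), collapse = "-"), attr(s, "band")] <-
      attr(s, "trial_mean")
  agg <- rowMeans(tab, na.rm = TRUE)
  out <- data.frame(pair = pairs, tab, aggregate = agg,
                    label = classify_valence(agg, ...),
                    row.names = NULL, check.names = FALSE)
  out
}
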