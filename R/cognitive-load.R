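#' Windowed band power (Welch-type periodogram)
#'
#' Splits the recording into Hann-tapered windows (default 2 s, 50% overlap)
#' and integrates the one-sided periodogram over each half-open band
#' `[lo, hi)`. Normalization is power-exact: a sinusoid of amplitude `a`
#' whose frequency sits on the window's frequency grid contributes `a^2/2`
#' to its band. Windows whose samples are more than 10% missing (alignment
#' padding) are dropped (`NA` power); smaller gaps are linearly interpolated
#' before the transform.
#'
#' @param rec An [eeg_recording()] (or [eda_recording()]).
#' @param bands Named list of [band_definition()]s, or a single band.
#' @param window Analysis window length in seconds (default 2). A hard error
#'   is raised below one cycle of the lowest band edge; windows shorter than
#'   two cycles draw a warning since the estimate degrades (four or more
#'   cycles are recommended for stable estimates).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return A `power_series` object: window times plus a
#'   `windows x channels x bands` power array in muV^2.
#' @export
band_power <- function(rec, bands = default_bands(), window = 2,
                       overlap = 0.5) {
  if (inherits(bands, "band_definition")) bands <- list(bands)
  names(bands) <- vapply(bands, `[[`, "", "name")
  fs <- rec$rate
  for (b in bands) {
    if (b$hi > fs / 2)
      stop("band '", b$name, "' exceeds Nyquist", call. = FALSE)
    if (window * b$lo < 1)
      stop("window too short: < 1 cycle of band '", b$name, "' (lo = ",
           b$lo, " Hz)", call. = FALSE)
    if (window * b$lo < 2)
      warning("window holds < 2 cycles of band '", b$name,
              "'; power estimate will be coarse", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)",
                                        call. = FALSE)
  n <- round(window * fs)
  if (n > nrow(rec$values)) stop("window longer than recording",
                                 call. = FALSE)
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, nrow(rec$values) - n + 1L, by = hop)

  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))   # periodic Hann
  sw2 <- sum(w^2)
  freqs <- (seq_len(n) - 1L) * fs / n
  half <- seq_len(floor(n / 2) + 1L)
  bins <- lapply(bands, function(b) which(freqs[half] >= b$lo &
                                            freqs[half] < b$hi))

  chans <- colnames(rec$values)
  power <- array(NA_real_, c(length(starts), length(chans), length(bands)),
                 dimnames = list(NULL, chans, names(bands)))
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + n - 1L)
    for (ci in seq_along(chans)) {
      x <- rec$values[idx, ci]
      nas <- is.na(x)
      if (any(nas)) {
        if (mean(nas) > 0.1) next                     # dropped window
        x <- as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
      }
      X <- fft(x * w)
      p <- Mod(X[half])^2
      scale <- ifelse(freqs[half] == 0 | freqs[half] == fs / 2, 1, 2)
      dens <- scale * p / (n * sw2)
      for (bi in seq_along(bands))
        power[wi, ci, bi] <- sum(dens[bins[[bi]]])
    }
  }
  t0 <- rec$t0 + (starts - 1L) / fs
  structure(list(t0 = t0, t1 = t0 + window, center = t0 + window / 2,
                 power = power, channels = chans, bands = bands,
                 window = window, overlap = overlap, log_relative = FALSE),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series: %d windows (%g s, %g%% overlap) x %d ch x %s%s>\n",
              length(x$center), x$window, 100 * x$overlap, length(x$channels),
              paste(band_names(x), collapse = "/"),
              if (isTRUE(x$log_relative)) ", log rel. to rest" else ""))
  invisible(x)
}

band_names <- function(ps) dimnames(ps$power)[[3]]

# Total power per window and channel: sum over the disjoint canonical bands,
# skipping the alpha sub-bands so alpha content is not double counted.
total_power_matrix <- function(ps) {
  use <- setdiff(band_names(ps), c("alpha1", "alpha2"))
  if (!length(use)) use <- band_names(ps)
  apply(ps$power[, , use, drop = FALSE], c(1, 2), sum)
}

#' Hemispheric asymmetry index
#'
#' The cognitive-load statistic: the difference of the log power of the left
#' and right homologous channels, divided by the log of their total power,
#'
#' `AI = (ln P_L - ln P_R) / ln(P_L + P_R)`
#'
#' Natural logarithms are used throughout. Higher asymmetry reflects stronger
#' workload; low asymmetry reflects avoidance/relaxation. The index is
#' undefined when the total power is near 1 muV^2 (log denominator near 0);
#' such windows return `NA` rather than an exploding value. Note the index is
#' *not* invariant to rescaling both powers, since the denominator changes.
#'
#' @param p_left,p_right Band power of the left / right channel (muV^2),
#'   both strictly positive. Vectorized.
#' @param guard Denominator magnitude below which the index is marked
#'   invalid (default `1e-6`).
#' @return Numeric vector of asymmetry indices (`NA` where invalid).
#' @export
asymmetry_index <- function(p_left, p_right, guard = 1e-6) {
  if (any(p_left <= 0, na.rm = TRUE) || any(p_right <= 0, na.rm = TRUE))
    stop("powers must be strictly positive", call. = FALSE)
  denom <- log(p_left + p_right)
  ai <- (log(p_left) - log(p_right)) / denom
  ai[abs(denom) < guard] <- NA_real_
  ai
}

#' Asymmetry series for a homologous pair
#'
#' Applies [asymmetry_index()] window-by-window to one left/right electrode
#' pair in one band (or to the summed total power with `band = "total"`).
#'
#' @param power A `power_series` from [band_power()] (raw power, not
#'   log-relative).
#' @param left,right Channel labels; must be 10-20 homologs from the pair
#'   registry.
#' @param band Band name present in `power`, or `"total"`.
#' @param pairs Homolog registry (default [homologous_pairs()]), overridable
#'   for non-standard montages.
#' @return An `asymmetry_series` data frame: window centers, `ai` values,
#'   `valid` flags; attributes `pair` and `band`.
#' @export
asymmetry_series <- function(power, left, right, band = "alpha",
                             pairs = homologous_pairs()) {
  stopifnot(inherits(power, "power_series"))
  if (isTRUE(power$log_relative))
    stop("asymmetry requires raw power, not baseline-normalized log power",
         call. = FALSE)
  if (!(left %in% names(pairs)) || !identical(unname(pairs[[left]]), right))
    stop("(", left, ", ", right, ") is not a registered homologous pair",
         call. = FALSE)
  for (ch in c(left, right))
    if (!ch %in% power$channels)
      stop("channel '", ch, "' not present", call. = FALSE)
  if (band == "total") {
    tot <- total_power_matrix(power)
    pl <- tot[, left]; pr <- tot[, right]
  } else {
    if (!band %in% band_names(power))
      stop("band '", band, "' not present", call. = FALSE)
    pl <- power$power[, left, band]
    pr <- power$power[, right, band]
  }
  ok <- is.finite(pl) & is.finite(pr) & pl > 0 & pr > 0
  ai <- rep(NA_real_, length(pl))
  ai[ok] <- asymmetry_index(pl[ok], pr[ok])
  structure(data.frame(center = power$center, ai = ai,
                       valid = ok & is.finite(ai)),
            pair = c(left, right), band = band,
            class = c("asymmetry_series", "data.frame"))
}

#' Cognitive-load index series
#'
#' Folds a frontal asymmetry series into the cognitive-load sign convention:
#' `CL = -|AI|`, so that rising workload appears as a negative fluctuation.
#' Only the frontal pairs (F3, F4) and (Fp1, Fp2) are accepted.
#'
#' @param frontal_asym An [asymmetry_series()] for a frontal pair.
#' @return Data frame with window centers and `cl` values (class
#'   `cl_series`).
#' @export
cl_index <- function(frontal_asym) {
  stopifnot(inherits(frontal_asym, "asymmetry_series"))
  pair <- attr(frontal_asym, "pair")
  if (!pair[1] %in% c("F3", "Fp1"))
    stop("cognitive load is defined for frontal pairs (F3,F4)/(Fp1,Fp2), got (",
         paste(pair, collapse = ","), ")", call. = FALSE)
  structure(data.frame(center = frontal_asym$center,
                       cl = -abs(frontal_asym$ai),
                       valid = frontal_asym$valid),
            pair = pair, band = attr(frontal_asym, "band"),
            class = c("cl_series", "data.frame"))
}

#' Total cognitive load of one electrode
#'
#' Per-electrode activation summary relative to rest: the time average over
#' windows of the log total power (summed over the disjoint canonical bands)
#' minus the resting-state mean log total power at the same electrode, in
#' natural-log units. Zero means task power equals resting power; 1 means
#' the task power is `e` times the resting power.
#'
#' @param power Task `power_series` (raw power).
#' @param electrode Channel label.
#' @param resting Resting-state `power_series` with the same channel.
#' @return Scalar TCL (natural-log units).
#' @export
total_cl <- function(power, electrode, resting) {
  stopifnot(inherits(power, "power_series"), inherits(resting, "power_series"))
  if (!electrode %in% power$channels)
    stop("electrode '", electrode, "' not present in task power",
         call. = FALSE)
  if (!electrode %in% resting$channels)
    stop("electrode '", electrode, "' not present in resting reference",
         call. = FALSE)
  task_tot <- total_power_matrix(power)[, electrode]
  rest_tot <- total_power_matrix(resting)[, electrode]
  task_tot <- task_tot[is.finite(task_tot) & task_tot > 0]
  rest_tot <- rest_tot[is.finite(rest_tot) & rest_tot > 0]
  if (!length(task_tot) || !length(rest_tot))
    stop("no valid windows for electrode '", electrode, "'", call. = FALSE)
  mean(log(task_tot)) - mean(log(rest_tot))
}

#' Global cognitive-load summary
#'
#' Computes the per-electrode total cognitive load ([total_cl()]) for every
#' channel and summarizes the distribution for box-plot style reporting:
#' median, quartiles, 1.5 IQR whisker bounds and sample skewness.
#'
#' @param power Task `power_series`.
#' @param resting Resting-state `power_series`.
#' @return A `cl_summary`: list with `tcl` (named per-electrode vector) and
#'   `summary` (one-row data frame).
#' @export
global_cl <- function(power, resting) {
  stopifnot(inherits(power, "power_series"))
  if (!length(power$channels)) stop("empty power series", call. = FALSE)
  tcl <- vapply(power$channels, function(ch) total_cl(power, ch, resting),
                numeric(1))
  structure(list(tcl = tcl, summary = distribution_summary(tcl)),
            class = "cl_summary")
}

# Box-plot style description of a sample: median, type-7 quartiles,
# 1.5 IQR whiskers (clamped to observed points), sample skewness.
distribution_summary <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  data.frame(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
             whisker_lo = lo, whisker_hi = hi,
             skewness = sample_skewness(x), n = length(x))
}

#' @export
print.cl_summary <- function(x, ...) {
  cat("<cl_summary>\nPer-electrode TCL:\n")
  print(round(x$tcl, 4))
  cat("Distribution:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Upper envelope of an asymmetry series with event markers
#'
#' Traces the upper envelope of a windowed asymmetry series through its local
#' maxima (linear interpolation between support points, endpoints included)
#' and projects Collision events onto the nearest window center, for
#' per-trial workload displays.
#'
#' @param series An [asymmetry_series()] (or `cl_series`).
#' @param events Optional [event_log()] on the same timebase; `Collision`
#'   rows are projected.
#' @return An `envelope_series` data frame: `center`, `value` (underlying
#'   series), `envelope`; attribute `markers` (data frame of projected
#'   events).
#' @export
asymmetry_envelope <- function(series, events = NULL) {
  vals <- if ("ai" %in% names(series)) series$ai else series$cl
  centers <- series$center
  ok <- is.finite(vals)
  if (sum(ok) < 3)
    stop("series shorter than 3 valid windows", call. = FALSE)
  x <- centers[ok]; y <- vals[ok]
  n <- length(y)
  interior <- which(y[2:(n - 1)] >= y[1:(n - 2)] &
                      y[2:(n - 1)] >= y[3:n]) + 1L
  support <- sort(unique(c(1L, interior, n)))
  env <- approx(x[support], y[support], xout = centers, rule = 2)$y

  markers <- NULL
  if (!is.null(events)) {
    coll <- events[events$event == "Collision", , drop = FALSE]
    if (nrow(coll)) {
      idx <- vapply(coll$timestamp,
                    function(tt) which.min(abs(centers - tt)), integer(1))
      markers <- data.frame(label = coll$event, time = coll$timestamp,
                            center = centers[idx], value = env[idx])
    }
  }
  structure(data.frame(center = centers, value = vals, envelope = env),
            markers = markers, pair = attr(series, "pair"),
            band = attr(series, "band"),
            class = c("envelope_series", "data.frame"))
}

#' Visual-cortex asymmetry
#'
#' Occipital (O1/O2) hemispheric analysis: the asymmetry index of the total
#' power per window, the mean recovered log power ratio `ln(P_O1 / P_O2)`,
#' and the per-electrode total cognitive load of O1 and O2 relative to rest.
#'
#' @param power Task `power_series` containing O1 and O2.
#' @param resting Optional resting `power_series` (required for the TCL
#'   component).
#' @return List with `asym` (an [asymmetry_series()] on total power),
#'   `ln_ratio_mean` (mean `ln(P_O1/P_O2)` over valid windows) and `tcl`
#'   (named vector for O1, O2; `NULL` when `resting` is missing).
#' @export
vc_asymmetry <- function(power, resting = NULL) {
  stopifnot(inherits(power, "power_series"))
  for (ch in c("O1", "O2"))
    if (!ch %in% power$channels)
      stop("missing occipital channel '", ch, "'", call. = FALSE)
  asym <- asymmetry_series(power, "O1", "O2", band = "total")
  tot <- total_power_matrix(power)
  ok <- is.finite(tot[, "O1"]) & is.finite(tot[, "O2"]) &
    tot[, "O1"] > 0 & tot[, "O2"] > 0
  ln_ratio <- mean(log(tot[ok, "O1"]) - log(tot[ok, "O2"]))
  tcl <- NULL
  if (!is.null(resting))
    tcl <- c(O1 = total_cl(power, "O1", resting),
             O2 = total_cl(power, "O2", resting))
  list(asym = asym, ln_ratio_mean = ln_ratio, tcl = tcl)
}
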