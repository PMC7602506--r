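# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Every stochastic component draws through this so
# substreams never perturb each other.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based substream derivation: a fixed prime stride per named stream,
# kept inside 32-bit integer range.
substream_seed <- function(seed, stream) {
  ids <- c(eeg = 1L, eeg_phase = 2L, eeg_noise = 3L, blinks = 4L,
           eda = 5L, eda_spont = 6L, eda_noise = 7L, ibi = 8L, events = 9L)
  id <- ids[[stream]]
  (as.integer(seed) %% 1000003L) * 1009L + id * 7919L
}

# Nearest odd sample count >= 3 for a window of `seconds` at `rate` Hz.
odd_window <- function(seconds, rate) {
  n <- max(3L, as.integer(round(seconds * rate)))
  if (n %% 2L == 0L) n <- n - 1L
  n
}

# Apply a signal::filtfilt zero-phase filter column-wise over a matrix.
filtfilt_matrix <- function(filt, x) {
  out <- apply(x, 2L, function(col) signal::filtfilt(filt, col))
  if (is.null(dim(out))) out <- matrix(out, ncol = ncol(x))
  dimnames(out) <- dimnames(x)
  out
}

# Sample skewness g1 = m3 / m2^(3/2).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a
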