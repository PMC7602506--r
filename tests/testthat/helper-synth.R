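# Shared fixtures: all built in code at test time.

rms <- function(x) sqrt(mean(x^2))

db_ratio <- function(out, ref) 20 * log10(rms(out) / rms(ref))

# Single- or multi-tone EEG recording on the given channels.
make_tone <- function(freqs, amps = 1, dur = 5, fs = 512, labels = "O1",
                      phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t + phase),
                      freqs, rep_len(amps, length(freqs))))
  vals <- matrix(rep(x, length(labels)), ncol = length(labels))
  eeg_recording(vals, rate = fs, labels = labels)
}

# Quiet trial configuration used in deterministic tests: no blinks, no
# spontaneous SCRs, no EDA noise.
quiet_config <- function(...) {
  trial_config(blink_rate = 0, spontaneous_scr_rate = 0, eda_noise_sd = 0,
               ...)
}

# band_power with the sub-second-lo delta warning silenced (expected for the
# default band set at the default 2 s window).
bp <- function(...) suppressWarnings(band_power(...))

# Bands without delta: no warnings at the 2 s default window.
bands_no_delta <- function() default_bands()[c("theta", "alpha", "beta",
                                               "gamma", "alpha1", "alpha2")]
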