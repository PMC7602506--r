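#' Default 16-channel 10-20 montage
#'
#' Channel labels of the recording montage: 16 scalp sites with an ear
#' reference. The left temporal site T7 completes the homologous pair for T8;
#' all other sites come in left/right mirror pairs plus the midline-free
#' prefrontal/occipital coverage used for cognitive-load and valence analysis.
#'
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "F7", "F3", "C3", "P3", "P7", "T7", "O1",
    "O2", "Fp2", "F8", "F4", "C4", "P4", "T8", "P8")
}

#' Homologous left/right electrode pairs
#'
#' Registry of mirror-symmetric 10-20 pairs used for hemispheric asymmetry
#' statistics. Names are the left-hemisphere sites, values their right
#' homologs.
#'
#' @return Named character vector, `left -> right`.
#' @export
homologous_pairs <- function() {
  c(Fp1 = "Fp2", F7 = "F8", F3 = "F4", C3 = "C4",
    T7 = "T8", P3 = "P4", P7 = "P8", O1 = "O2")
}

#' Construct a frequency-band definition
#'
#' Bands are half-open intervals `[lo, hi)` in Hz.
#'
#' @param name Band name.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `band_definition` object.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("invalid band edges for '", name, "': need 0 < lo < hi", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: [%g, %g) Hz>\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Default analysis bands
#'
#' delta \[0.5,4), theta \[4,7), alpha \[8,13), beta \[13,30), gamma \[30,45),
#' plus the lower/upper alpha sub-bands alpha1 \[7,10) and alpha2 \[10,13)
#' when `subbands = TRUE`. alpha1 is tied to response inhibition and
#' attentional demand, alpha2 to task difficulty; gamma is capped at 45 Hz so
#' the band clears the 50 Hz power-line notch. alpha1 deliberately overlaps
#' theta over 7-8 Hz, matching the conventional sub-band print edges.
#'
#' @param subbands Include alpha1/alpha2 sub-bands (default `TRUE`).
#' @return Named list of [band_definition()] objects.
#' @export
default_bands <- function(subbands = TRUE) {
  b <- list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 7),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 45)
  )
  if (subbands) {
    b$alpha1 <- band_definition("alpha1", 7, 10)
    b$alpha2 <- band_definition("alpha2", 10, 13)
  }
  b
}

# Synthesis centre frequencies: one sinusoid per band keeps analytic power
# checks exact. Values sit mid-band (alpha1 at 9, alpha2 at 11.5).
synthesis_band_centers <- function() {
  c(delta = 2, theta = 6, alpha1 = 9, alpha2 = 11.5, beta = 20, gamma = 38)
}

#' Electrode pairs used for valence assessment
#'
#' Right/left homolog pairs over the temporal, central, parietal and frontal
#' lobes: (T8,T7), (C4,C3), (P4,P3), (F4,F3). T8-T7 is the headline pair for
#' emotion assessment; occipital sites are excluded because the visual cortex
#' is analysed separately.
#'
#' @return List of `c(right, left)` character pairs.
#' @export
valence_pairs <- function() {
  list(c("T8", "T7"), c("C4", "C3"), c("P4", "P3"), c("F4", "F3"))
}
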