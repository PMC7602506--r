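---
title: "Methods: cognitive load and affect from multimodal mobility trials"
author: "navload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognitive load and affect from multimodal mobility trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navload)
```

## The measurement problem

Assistive navigation trials for visually impaired users produce three
loosely coupled physiological streams — a 16-channel EEG at 512 Hz (10-20
montage, ear reference), an electrodermal (EDA) stream at 16 Hz, and a
heart-rate / inter-beat series — together with a video-derived event log
(`Start`, `Collision`, `Find`, `Lost`, `TouchCane`, `Stop`, Unix-epoch
timestamps). The analysis questions are: how much mental effort does a
navigation condition (white cane vs. an audio/haptic/multimodal
sensory-substitution encoding) demand, what affective state does it induce,
and how does the autonomic nervous system respond. None of these is observed
directly; all are operationalized as statistics of band power, conductance
dynamics and beat-interval variability. This vignette documents the models,
the tunable parameters, and the design decisions behind each stage.

## Stream model and synchronization

Streams are stored in an HDF5 container (one group per stream, datasets
`time` and `values`, attributes `rate_hz`, `labels`) and annotations in a
two-column CSV (`event,timestamp`). All timestamps are epoch-anchored
seconds; every analysis window is half-open `[t0, t1)`.

Alignment to the trial timeline (the video length) is constant-offset only:
overruns are trimmed at the tail, shortfalls padded with `NA` markers that
propagate — they are never imputed — and any power window containing more
than 10% missing samples is dropped. Clock *drift* between acquisition
devices is out of scope; residual offsets larger than one sample at the
stream's rate are flagged in the alignment report, never silently corrected.
A stream overlapping the reference by less than 50% is treated as a gross
clock error and refused. Beat-event (`hr`) streams are irregular by nature
and are sliced by time window rather than trimmed/padded by sample count.

The default montage replaces a duplicated right-central channel found in
some acquisition configurations with the left temporal site T7, which the
valence pair set requires; this completes the eight mirror pairs
Fp1/Fp2, F7/F8, F3/F4, C3/C4, T7/T8, P3/P4, P7/P8, O1/O2.

## EEG conditioning

The chain is: broadband band-pass 0.5–100 Hz, 50 Hz power-line notch,
Savitzky-Golay artifact suppression, band decomposition, baseline
normalization. All filters are 4th-order Butterworth designs (2nd-order for
the ±1 Hz notch) applied forward and backward, so the chain is zero-phase —
a hard requirement when event markers are projected onto windowed series.
The gamma band is capped at 45 Hz so that it clears the notch.

Artifact suppression fits a cubic Savitzky-Golay trend over a 0.511 s
window (an odd sample count at 512 Hz) and flags samples whose residual
exceeds 5 median-absolute-deviations of the channel's residual. Two
refinements proved necessary beyond the plain flag-and-replace rule:
flagged runs are dilated by one eighth of the window on each side (transient
tails taper below any fixed threshold), and replacement values come from a
second smoothing pass computed on the already-suppressed series (otherwise
the replacement itself carries the transient's leakage). With both, a 50 ms
200 µV blink on a 10 µV alpha background leaves a residual below 10% of the
blink amplitude. The detector is explicitly a *brief-transient* suppressor:
transients long relative to the window (e.g. full 400 ms blinks) are partly
tracked by the polynomial fit and only attenuated, which is why frontal
cognitive-load statistics prefer F3/F4 over Fp1/Fp2 when both are available.
"Online" operation is relaxed to causal-window equivalence; offline analysis
is the use case.

Baseline normalization subtracts, per channel, the mean of a resting-state
recording. Whether the subtraction applies to raw amplitude or to power is
genuinely ambiguous; both modes are implemented. The pipeline default is
*power mode* (subtracting resting mean log band power), because every
downstream statistic is power-based; *literal mode* (time-series mean
subtraction) is retained for fidelity.

## Band power estimation

Power is estimated per analysis window with a Hann-tapered periodogram,
power-normalized so that a sinusoid of amplitude $a$ on the window's
frequency grid contributes exactly $a^2/2$ to its band. Bands are half-open
`[lo, hi)` bins of the one-sided spectrum.

The default window is **2 s with 50% overlap**. A 1 s window (1 Hz bins)
looks sufficient for the 3 Hz alpha sub-bands, but the Hann taper spreads an
on-bin tone over ±1 bin: a 9 Hz tone then leaks one sixth of its power into
the 10 Hz bin, which belongs to alpha2 under half-open binning, and the
alpha1/alpha2 split becomes structurally lossy. At 2 s (0.5 Hz bins) the
tone's triplet lies wholly inside its sub-band and the calibration is exact.
This resolution/tracking trade-off is the package's own choice; the window
is a parameter. A window should hold at least four cycles of a band's lower
edge for stable estimates; below two cycles the package warns, below one it
refuses. The delta band (lo = 0.5 Hz) at the default window is therefore a
coarse estimate, acceptable because no headline statistic reads delta alone
— it only enters the total-power sum, where the alpha sub-bands are excluded
to avoid double counting.

## Cognitive load

The asymmetry index $AI = (\ln P_L - \ln P_R)/\ln(P_L + P_R)$ uses natural
logarithms throughout. Two numerical edges are handled explicitly: the
formula is undefined where total power approaches 1 µV² (log denominator
near zero) — such windows are marked invalid rather than returning an
exploding value — and the index is *not* invariant to rescaling both powers
(the denominator changes), which a regression test pins so the behavior is
never "fixed" silently. The cognitive-load series is $-|AI|$, so workload
growth reads as a negative deflection; both frontal pairs are computed and
reported, since which one drives the headline index is not canonical.

Per-electrode total cognitive load (TCL) has no single canonical
operationalization; the package defines it as the time average of
baseline-normalized log total power — 0 when task equals rest, 1 when task
power is $e$ times resting power. This reading ties TCL to per-electrode
activation relative to rest and makes O1/O2 TCL directly comparable across
trials of different lengths. The global CL summary reports the
per-electrode TCL distribution as median, type-7 quartiles, 1.5·IQR
whiskers and sample skewness — the quantities a box-plot comparison reads.

Asymmetry envelopes are upper envelopes through local maxima with linear
interpolation (endpoints included, so a constant series has a flat
envelope), with `Collision` events projected to the nearest window center.

## Valence

$VS = \ln(PS_R/PS_L)$ per pair and band (alpha, beta, gamma). The
trial-level value is the mean of windowed VS, not the VS of mean powers —
the two differ whenever power fluctuates, and a test documents the
difference. Qualitative labels use fixed symmetric thresholds, |VS| < 0.05
neutral, 0.05–0.25 "low", above 0.25 full-strength; the labels are
config-exposed because any such cut is a reporting convention, not a
measurement. Aggregation order is windows → bands within a pair; a further
mean over trials or users is the caller's choice.

## Autonomic indices

EDA calibration is the affine map $y = p_1 x + p_2$ with identity defaults
(sensor-range-specific constants belong to the device datasheet). The
low-pass default is 1 Hz — the conservative end of the usable 1–5 Hz range,
given only 8 Hz of headroom at a 16 Hz stream — implemented zero-phase with
the endpoint-to-endpoint baseline removed before filtering and restored
after, so the tonic level does not masquerade as a step edge at the
recording boundaries.

The tonic/phasic split is a sliding **lower-decile** (10th percentile)
baseline over an 8 s window, with `tonic + phasic == input` exactly. A
sliding *median* at this window length absorbs roughly half of each
skin-conductance response (a standard bi-exponential SCR, 0.75 s rise / 4 s
decay, exceeds its half-amplitude for about half of an 8 s window centered
on the peak), which would bias every amplitude-based index downward by a
factor of ~2; the lower decile tracks tonic level and drift equally well but
rides under the SCR excursions, so phasic peaks retain the full response
amplitude. Full deconvolution of a sudomotor driver function is deliberately
out of scope: every downstream quantity (SCR count, amplitudes, index)
depends only on phasic extrema.

SCR detection scans the phasic component for local-minimum-to-local-maximum
excursions of at least 0.05 µS completed within 5 s, with a 1 s onset
refractory — standard electrodermal practice. The "global SCR index" is
reported as the mean SCR amplitude; because a count-rate reading of such an
index is equally defensible, count and rate per minute are always exported
alongside, so either interpretation is recoverable.

RMSSD is $\sqrt{\mathrm{mean}(\Delta IBI^2)}$ (ms); the task-vs-rest
contrast is the percent change $100 (task - rest)/rest$, which is only
antisymmetric around task = rest — an asymmetry of percent change that is
documented rather than hidden.

## The synthetic-trial generator

The generator emulates the acquisition: per channel, one sinusoid per band
(delta 2, theta 6, alpha1 9, alpha2 11.5, beta 20, gamma 38 Hz — single
tones keep analytic power checks exact) at configurable amplitudes
(defaults 20/10/10/8/5/2 µV), 1/f background noise (5 µV RMS), and 400 ms
raised-cosine blinks on Fp1/Fp2 (10/min, 200 µV). Injected left:right power
ratios $r$ scale the left channel of each pair by $\sqrt{2r/(1+r)}$ and the
right by $\sqrt{2/(1+r)}$, preserving pair mean power. EDA is tonic level
(2 µS) plus drift (0.02 µS/min), unit-peak bi-exponential SCRs at
configured onsets, Poisson spontaneous SCRs (2/min) and optional motion
noise; the IBI series is mean 800 ms with 25 ms Gaussian jitter (expected
RMSSD $\sqrt 2 \cdot 25$ ms), or a deterministic alternating test mode with
RMSSD exactly $2d$. All randomness flows from one seed through fixed
per-stream substreams, so adding a stream never perturbs another and equal
(config, seed) pairs are bit-identical. The resting-state reference
duration is a parameter (default 60 s).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: volume conduction and realistic source
mixing, non-stationary rhythm amplitudes, EMG broadband artifacts, sensor
dropout, pink-noise EDA drift, or respiratory sinus arrhythmia structure in
the beat series. Recovery results on synthetic trials bound the estimator's
numerical behavior, not its physiological validity.

## Problem sizes and verification

The test suite verifies closed-form values against independent hand
oracles, filter attenuations against generated tones, and parameter
recovery against generator ground truth: hemispheric ratios
$r \in \{1/4, 1/2, 1, 2, 4\}$ on 24 s two-channel trials (≥ 20 windows,
5 seeds each, ln-ratio within 10%), an occipital 6:1 ratio, and 3 injected
SCRs per trial across 20 seeds (exact count, amplitudes within 10%). The
end-to-end discrimination check runs 20 suites of paired conditions
(frontal alpha ratio 2 plus 3 spontaneous SCRs/min, versus null) with five
60 s trials per condition; 60 s × 5 is sized so that Poisson sampling of a
3/min schedule almost never leaves a majority of zero-event trials in a
group (tie probability ≈ 0.1%), keeping the ordering check a test of the
estimators rather than of event-count luck. The same quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Long (≥ window-length) blinks are only partially attenuated; ICA or
  regression-based ocular correction is out of scope.
* Constant-offset synchronization only; no clock-drift model.
* The theta/alpha1 overlap (7–8 Hz) follows the conventional sub-band print
  edges; a tone at 7.5 Hz is counted in both bands, and the disjoint
  total-power sum uses alpha, not the sub-bands.
* Descriptive statistics only: the pipeline compares conditions by medians,
  IQRs and skewness, and deliberately performs no hypothesis tests.
* EDA decomposition is baseline-subtraction, not driver deconvolution;
  amplitudes of strongly overlapping SCRs (< 10 s apart) are
  under-estimated.
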