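---
title: "Methods: synthetic pulsed-call scenes and the individuality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic pulsed-call scenes and the individuality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pulsecall` analyzes individuality in odontocete pulsed contact calls
recorded on a pair of hydrophones. This vignette documents the models
behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations. It states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` themselves
compute.

## The measurement model

A pulsed contact call is a train of broadband transients. Per call the
package measures five temporal parameters — the averaged inter-pulse
interval (IPI) over intervals led by pulses 11–20, the mirrored average
counted 11–20 from the last pulse, duration (first to last pulse peak),
pulse count, and pulse repetition rate `PRR = pulses / duration` — and
four spectral parameters of the middle pulse: peak frequency, the 10 dB
bandwidth, and its lower and upper edges, read from a Hamming-windowed
FFT-256 spectrum (1953 Hz bins at 500 kHz; 0.512 ms frames) averaged
over the 1.5 ms around the pulse peak, smoothed with a 5-point moving
window, and expressed in dB relative to the 6–170 kHz band maximum.
Spectral parameters are compared in 11–170 kHz because all callers share
a common ~6 kHz energy peak below 10 kHz.

Two indexing conventions are deliberate and tested, since either could
be read from the verbal definition:

* *IPI indexing.* Interval *i* spans pulses *i* → *i+1*, so "pulses
  11–20" selects the ten intervals with leading index 11..20, and the
  mirrored set is (n−20)..(n−11). Calls of 12–20 pulses average the
  available subset and are flagged `truncated`; calls under 12 pulses
  get `NA` averages (flagged `missing`) while duration and PRR are still
  returned. Real corpora contain such calls (minimum observed pulse
  counts are near 19), so they must flow through the pipeline rather
  than error.
* *Middle pulse.* At even pulse counts the middle pulse is `ceiling(n/2)`
  (the earlier candidate).

## Individuality statistics

For each parameter, `CVb = 100·SD/mean` over all calls pooled and, per
individual, the small-sample-corrected `CVw = 100·(SD/mean)·(1+1/(4n))`.
The potential for individual coding is `PIC = CVb / mean(CVw)`; PIC > 1
flags parameters more variable between than within individuals. Sample
SDs use the n−1 denominator throughout. Reported tables round CVs and
PIC to two decimals and classification rates to one (round-half-up).

Before discriminant analysis the nine candidate parameters are screened:
variance inflation factors `VIF_j = 1/(1−R²_j)` with iterative removal
of the worst feature above 20 (perfect collinearity — e.g. the 10 dB
bandwidth, which is exactly `upper − lower` — counts as infinite and is
removed first); robust Mahalanobis distances from an MCD fit flag
multivariate outliers at the 0.975 chi-square quantile but never drop
rows (dropping is an explicit configuration, mirroring analyses that
retain outliers except a single extreme point). Features with zero
variance inside any class are excluded from the multivariate stages:
they would make that class's covariance singular, and on synthetic data
this happens when a caller's 10 dB band edge pins to the analysis-band
boundary. The MCD scatter can itself be singular on bin-quantized
spectral features, so outlier flagging is advisory (it degrades to a
message rather than aborting the analysis).

Classification uses quadratic discriminant analysis (per-class Gaussian
with its own covariance — group tests on real-type data reject both
multivariate normality and covariance homogeneity, which is why the
quadratic rather than linear rule is the default) with priors
proportional to class sample sizes, evaluated by jack-knife
leave-one-out cross-validation via `MASS::qda(CV = TRUE)`; the test
suite holds it equal to a brute-force per-fold refit oracle. Class sizes
are balanced beforehand by subsampling classes above a cap (default: the
second-largest class size, i.e. only the dominant class is reduced).
Forward stepwise ranking adds, at each step, the feature that maximizes
the LOOCV correct fraction; the best single feature is always taken and
later steps must improve the criterion by at least 0.05. Box's M
(chi-square approximation) tests covariance homogeneity, and Mardia's
skewness/kurtosis on within-class-centred residuals stands in for an
unspecified multivariate Shapiro–Wilk variant. The Kruskal–Wallis test
is tie-corrected (`stats::kruskal.test`).

## The synthetic generator

No recordings are distributed with studies of this kind, so every stage
is validated against a ground-truthed generator.

**IPI contours.** Each caller has a piecewise-linear template: an
initial plateau, then a linear transition clamped at a terminal IPI. Per
interval, additive Gaussian jitter; for the calf-like profile an
additional bounded random walk reproduces contours that fluctuate over
the call rather than repeat a stereotype. The whole contour is then
scaled by a lognormal per-call "rendition" factor. The scale factor is
multiplicative and lognormal for two reasons: an additive shift can push
the adult male's ~2.9 ms early IPIs through zero, and observed per-call
averaged IPIs spread asymmetrically (maxima far above the mean, minima
close below it), which a lognormal reproduces with one parameter. IPIs
are floored at 0.1 ms. With all noise scales zero the contour is exactly
the template, which anchors the template-fidelity tests.

**Pulse waveform.** Pulses are synthesized in the frequency domain as an
asymmetric Gaussian magnitude spectrum passing through the caller's peak
frequency and both of its printed 10 dB band edges, with linear phase
(symmetric transient, time peak normalized to 1). A symmetric Gabor atom
cannot represent these spectra: a caller with peak 29 kHz and a 111 kHz
band folds across DC and peaks at the wrong frequency, and a symmetric
band around 113 kHz would extend past the 170 kHz recording edge
although the measured upper edge is 148 kHz. The envelope keeps a
symmetric core (±5 kHz) around the peak, wider than the 5-point
smoother, so the *measured* (smoothed) peak frequency lands on the
profile setting — the profile parameters are meant to be what the
measurement procedure reads back. Each pulse also carries a common
low-band (~6 kHz) component at −10 dB *spectral* level (atoms of
different duration have different per-bin density, so the scaling is by
spectral peak magnitude, not time amplitude), and the adult-male profile
adds a continuous ~13 kHz tonal component at −40 dB time amplitude: a
tone concentrates its energy in a single bin, so even −40 dB produces a
dominant narrowband line in long-window spectra while staying below the
pulse-detection threshold and below the pulse's own per-bin spectral
peak.

**Per-call spectral variation.** One lognormal directivity factor per
call scales the whole spectral envelope (dispersion 0.30 by default),
with the upward excursion capped at +15%: high frequencies are the most
directional, so off-axis reception shifts received spectra downward
rather than above the recorded band. Together with measurement noise
this yields emergent within-individual peak-frequency CVs in the
30–40% range, the level reported for captive-beluga middle-pulse
spectra; the generator parameter is calibrated to that emergent level,
not added on top of it.

**Default profile pack.** `default_profile_pack()` encodes five callers
— adult male `H` (low initial IPIs rising steeply, tonal line), adult
females `T` and `G`, sub-adult `N` (all stereotyped), calf `M`
(high-jitter, random-walk contour) — with temporal means, between-call
SDs, pulse-count distributions, spectral peaks and 10 dB edges taken
from the published per-individual statistics of a captive group, and
−6 dB source level for the two weakest callers. These defaults are test
fixtures emulating the study conditions, not biological claims.

**Sessions.** Two hydrophones 7.5 m apart at 1 m depth; the isolated
caller draws a position per call inside the isolation-pool region, all
others inside a group region beyond the second hydrophone. Propagation
is straight-path delay with 1/r spreading only — no multipath (beyond
the synthetic echo used in the reflection-rejection test) and no
absorption. Noise is white Gaussian plus a low-passed (<5 kHz) component
that elevates the low-frequency floor, mirroring the band that is
excluded from analysis; the SNR parameter (default 20 dB) is the ratio
of the weakest received pulse amplitude to the broadband noise SD — no
amplitude statistics are published for these calls, so SNR is a free
scene parameter. Rendering is bit-reproducible for a fixed scene seed.

## Detection and attribution

The detector front end is the analytic-signal envelope of a band-passed
channel (4th-order zero-phase Butterworth). Three threshold conventions
coexist deliberately:

* `detect_call_onset` keeps the classical rule — first envelope crossing
  of `factor ×` noise level, default factor 3. At a 150 kHz analysis
  bandwidth, however, the noise-envelope *maximum* over a one-second
  call is roughly 4× its median, so a 3× threshold is routinely crossed
  by noise between pulses.
* `detect_pulses` therefore uses a 5× factor for per-pulse peaks
  (configurable in `pulse_params()`), plus a refractory minimum IPI of
  1.0 ms (observed PRR maxima near 250 pulses/s leave margin), echo
  rejection (a candidate 0.1–1.0 ms after a stronger pulse and below 0.7
  of its amplitude is discarded — a configurable surrogate for manual
  reflection correction), and a single secondary pass that recovers one
  low-amplitude pulse inside gaps of 1.7–2.4× the *local* median IPI
  (±5 neighbouring intervals), searching only the central 40% of the gap
  at half the threshold. The median must be local because slow contour
  ramps legitimately span a 2.7× IPI range; the gap-ratio window is
  bounded above because much longer gaps are pauses, not missed pulses.
* The session pipeline (`analyze_session`) detects on a 20–170 kHz
  envelope (`detect_band`): pulse energy is broadband across that range,
  while the ~13 kHz tonal component and the elevated low-frequency floor
  would otherwise ride above a global threshold on loud calls (received
  amplitude varies severalfold across positions and channels). Spectral
  measurement still uses the full 6–170 kHz band.

Call segmentation groups supra-threshold peaks separated by under 50 ms
of quiet, discarding clusters of fewer than 5 peaks — single noise
excursions can cross any practical threshold, but they do not form
trains.

TDOA is the lag maximizing the cross-correlation of the two channels'
baseline-subtracted envelopes (soft-thresholded at 3× the envelope
median so that the pulse peaks, not the noise floor, carry the
correlation), refined by parabolic interpolation; an onset-difference
method is provided as an alternative. A normalized correlation peak
below 0.65 flags the call ambiguous — two overlapping equal-energy calls
from different directions produce a coefficient near 0.5, a single clean
call near 1. With two sensors, attribution is an interval test: the
isolation-zone TDOA range is computed from the scene geometry on a
position grid, and verdicts are `isolated` / `other` / `ambiguous` with
a 0.2 ms boundary tolerance (no numeric ambiguity criterion is
established for this design; the tolerance is configurable). Ambiguous
calls are counted but excluded from per-individual statistics.

## Categorization

Aural/visual call-type judgement is replaced by a rule-based surrogate
over measured descriptors: duration (envelope above 10% of its peak),
a tonality score (energy fraction around the five largest peaks of the
cepstrally smoothed spectrum, threshold 0.6), broadband coverage
(fraction of 6–170 kHz bins within 25 dB of the maximum, threshold 0.4)
and a disjoint spectral-component count. Rules apply in order: broadband
pulsed ≥ 150 ms → `PS1` (shorter → `O`); two concurrent non-overlapping
components with some broadband content → `C1`; tonal < 150 ms → `S`,
otherwise `W`; else `O`. The broadband test precedes the component count
because a pulsed call's common low-band peak can sit apart from its main
high-frequency lobe without making the call a combined type. Reported
category shares are floored integer percentages (conservative
truncation, matching how the predominant-type share is quoted); with k
categories the floored shares sum to within [100−k, 100].

## Problem sizes and numerical choices

The validation corpus is 30 calls per individual at 20 dB SNR (150
calls) for detection recovery and the statistics, and ten 10-call
two-hydrophone sessions (100 calls) for attribution — sizes chosen so
the whole suite and the acceptance script each run in a few minutes on
one CPU while keeping binomial noise on the recovery rates near one
percentage point. Envelope FFTs pad to 2-3-5-smooth lengths; pulse peak
times are quantized to the sample grid (2 µs at 500 kHz), which bounds
jitter-free IPI recovery error by one sample period; spectra floor at
the smallest double before dB conversion; the 10 dB band is scanned
outward from the first maximal bin (ties resolve to the lowest
frequency, flat spectra are flagged degenerate).

## What passing tests do and do not show

The generator reproduces the *structure* of the study conditions —
individually stereotyped IPI contours vs. a fluctuating calf, shared
low-band energy, individual spectral envelopes with realistic
within-individual spread, a tonal line for one caller, two-hydrophone
geometry with an isolation zone — and the package's statistics recover
that structure (PIC above 1 for identity-bearing parameters, an
IPI-derived feature ranked first, LOOCV far above the permutation
null). It does not emulate multipath reverberation, frequency-dependent
absorption, beam steering within a call, overlapping choruses, vessel
noise, or behavioural call-rate variation; nor does any synthetic result
certify performance on real recordings — the honest claims are formula
correctness (held to independent oracles) and faithful recovery of known
ground truth under the stated scene model. Results printed from the
published summary tables (category shares, call totals, PIC ratios from
CVb / mean-CVw pairs, FFT resolutions, ANOVA degrees of freedom) are
exact arithmetic and reproduce regardless of the synthetic model.
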