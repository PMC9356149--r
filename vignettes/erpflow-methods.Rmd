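---
title: "Methods: automated ERP preprocessing and its synthetic validation"
author: "erpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated ERP preprocessing and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and pipeline order

`erpflow` automates the preprocessing chain used for event-related potential
(ERP) analyses of continuous multichannel EEG. A batch run
(`runPipeline()`) applies, in fixed order: loading and channel selection; a
100 Hz lowpass; multi-taper line-noise removal; optional downsampling;
composite bad-channel detection; wavelet-threshold artifact correction; the
user's ERP band filter; segmentation with baseline correction and optional
within-segment repair; amplitude/joint-probability segment rejection;
spherical-spline interpolation of removed channels; optional re-referencing;
and condition splitting. Two quality-report tables (data quality and
pipeline quality) are written per batch. The 100 Hz lowpass precedes
artifact handling so that bad-channel statistics and wavelet thresholds are
computed on the band that contains neural signal.

Internally, sample indices are 0-based and event onsets are stored as
integer samples; every user-facing quantity is in seconds or milliseconds
(ms-to-sample conversion is `round(ms * rate / 1000)`, so segmentation is
deterministic). Epoch windows are half-open in samples.

# Line-noise removal

Mains interference is modelled as a deterministic sinusoid and removed by
regression rather than notch filtering, which would also delete genuine
activity at neighbouring frequencies. In 4 s windows stepped by 1 s, each
channel is projected onto Slepian tapers (half-bandwidth 2 Hz, giving
`K = floor(2 * 2 * 4) - 1 = 15` tapers); the complex sinusoid amplitude at
the scan frequency (target ± 2 Hz, on the 0.25 Hz periodogram grid)
maximizing Thomson's harmonic F statistic is estimated, and its
significance assessed against F(2, 2K−2). The fitted sinusoid is subtracted
only in windows with `p < 0.01`; complex estimates are smoothed across
windows with an exponential kernel (`tau = 100` window steps) before
subtraction, and overlapping windows are blended with a linear cross-fade.

Smoothing pools *all* windows, not only significant ones: an insignificant
window's estimate is still an unbiased estimate of a near-zero amplitude,
and pooling it both stabilizes genuine line components and dilutes spurious
fits. This is what makes a second pass over already-cleaned data nearly a
no-op (the residual 60 Hz power changes by well under 5 %). A `legacy`
flag disables the smoothing but maps to the same estimator otherwise.

The Slepian tapers themselves are computed from the standard symmetric
tridiagonal formulation by Sturm-sequence bisection plus inverse iteration,
which costs O(KN) instead of a full eigendecomposition; the tests pin the
resulting sequences against reference values.

# Bad-channel detection

Four criteria run in sequence, each on the survivors of the previous one:

1. **Flatline** — a contiguous run of near-zero first differences lasting
   strictly longer than 5 s.
2. **Spectral outliers** — mean log10 Welch power over 1–100 Hz, z-scored
   across channels; flagged above +3.5 or below −5 SD. The band stops at
   100 Hz because the pre-clean lowpass has removed content above it. The
   asymmetric thresholds reflect that artifact inflates power while only
   channels adjacent to the online reference legitimately sit far below the
   mean. The pass runs twice (flag, drop, re-estimate, flag again; union).
3. **Line-noise ratio** — log ratio of power at the mains frequency ± 1 Hz
   to the rest of the band, robust-z (median/MAD) above 6.
4. **Correlation** — per 1 s window, each channel's best absolute
   correlation with any other channel; flagged when the mean best
   correlation falls below 0.8.

A caution that shaped the tests: with a z threshold of +3.5, a *single*
extreme outlier among n channels can reach at most `(n−1)/sqrt(n)` SD, so
the spectral criterion is only meaningful for channel counts around 15 and
above. The planted-defect benchmark therefore uses 39-channel files
(`badChannelBenchmark()`, 20 files, 780 channel decisions), on which the
detector's recall and false-positive rate are asserted at ≥ 0.9 and ≤ 0.02.

# Wavelet-threshold artifact correction

Continuous data are decomposed per channel with an undecimated
(maximal-overlap) coiflet-4 transform to `round(log2(rate)) − 1` levels, so
the coarsest detail band reaches about 1 Hz. Each detail level is split at
the universal threshold `lambda_j = s_j * sqrt(2 ln N)` with the robust
level noise scale `s_j = median(|d_j|)/0.6745`. The *supra-threshold*
content is the artifact: in soft mode the excess `sign(w) max(|w|−λ, 0)` is
removed (the retained coefficient is clipped at λ); in hard mode any
coefficient beyond λ is removed entirely. The approximation band is left
untouched by default so slow cortical activity survives. Soft mode suits
low-artifact data; hard mode removes more variance on every input
(coefficientwise `|retained_hard| ≤ |retained_soft|`) and suits
high-artifact recordings. `cleaned + removed == input` holds exactly, and
the removed series feeds the quality reports.

Numerical choices: the signal is extended by a full reflection (to length
2n) before the circular transform — a *truncated* reflection would leave a
discontinuity at the circular wrap that injects spurious fine-scale
coefficients at the signal edges, which is also why a power-of-two pad
length is neither needed nor used. Thresholds use `N = 2n`.

Two behavioural limits are worth knowing. First, the robust noise scale is
estimated from the data themselves, so on a *noise-free* periodic signal
the signal's own coefficients dominate the level statistics and are partly
removed; the amplitude-preservation guarantees hold on data with an
EEG-scale background (the condition the correction is designed for), and
the tests state them that way. Second, time-locality is bounded by the
coarse-level filter support — an undecimated coiflet-4 at level 9 spans
seconds — so a transient's influence on the correction decays over about a
second, not within tens of milliseconds; the locality test asserts < 1 µV
RMS leakage beyond 1 s from a planted 500 µV pulse.

# Filtering

The ERP band filter is either a zero-phase Hamming windowed-sinc FIR
(tap count `ceil(3.3 rate / tb)` from the transition width
`tb = min(max(0.25 f, 2 Hz), f)` of the narrower edge, applied by
delay-compensated symmetric convolution with reflection padding) or a
Butterworth cascade applied forward–backward. The published IIR order rule
`3 * floor(rate / highpass)` produces orders in the thousands at ERP
cutoffs (rate 1000, highpass 0.1 Hz → 30000) and cannot be realized; the
order is capped at 8 and the filter applied as analytically designed
second-order sections, because transfer-function polynomials of high-order
Butterworth designs at relative cutoffs of 1e-4 are numerically singular.
The section design is pinned against an independent reference
implementation in the tests. Narrow QC probe bands use a fixed 1 Hz
transition width instead of the ERP heuristic, which is far too loose to
separate a probe at 55 Hz from a line at 60 Hz.

# Segmentation, repair and rejection

Epochs are cut around matching event markers with an optional
timing-offset correction, baseline-corrected by mean subtraction over the
pre-stimulus window, and optionally repaired within segments: per (trial,
channel), four statistics — variance, median absolute successive
difference, amplitude range, deviation from the channel's mean amplitude —
are z-scored per channel across trials, and any |z| > 3 flags the pair for
spherical-spline interpolation from that trial's clean channels (trials
with fewer than four usable channels are marked for rejection instead).

Segment rejection marks trials by amplitude bounds (±150 µV suggested for
child-to-adult data, ±200 µV for infants; the bounds are µV — the
magnitudes only make sense on that scale) and/or joint probability: per
channel, the trial's summed sample log-density (256-bin histogram with
add-one smoothing over the channel's pooled samples — deterministic and
parameter-free) is z-scored across trials, and per trial across channels;
|z| > 3 on either axis marks the trial. Both z comparisons are two-sided.
All marks are applied in a single step to the `kept` flags; nothing is
deleted, so reports can always reconcile counts. Restricting evaluation to
a region of interest can only retain more trials, which the tests assert
as an inequality.

# Spherical-spline interpolation and re-referencing

Scalp potentials are interpolated with the Legendre-series kernel
`g(cos θ) = (1/4π) Σ_{n=1..7} (2n+1)/(n(n+1))^m P_n(cos θ)` with stiffness
`m = 4` — the standard choice for scalp potentials — and `1e-5` added to
the system diagonal for conditioning. Seven series terms follow the design
choice of truncating at order 7. The estimate is linear in the data,
reproduces constants exactly and first-degree harmonics to < 5 % RMS.
Re-referencing subtracts the mean of all channels or of a named subset; a
known prior online reference can be recovered as an appended zero channel
before subtraction.

# The simulated-VEP benchmark

`synthesizeEpochs()` builds a three-component visual evoked potential from
Gaussian peaks (N1: centre 170 ms, width 60, −7.5 µV, slope −2; P1: 200,
60, +7.5, −2; N2: 235, 100, −10, −3; centres include a 100 ms shift that
creates the pre-stimulus baseline). The Gaussian width is interpreted as
`sigma = width/6`; under this rule the summed first-epoch waveform has its
150–190 ms minimum at −7.42 µV, matching the benchmark design's printed
simulated N1 to 0.03 %, which is what fixed the interpretation. The
window positions (150–190 etc.) are stated on the simulated-data axis;
`vepMeasureWindows(offset_ms = -100)` expresses them on the stimulus-locked
axis after segmentation. "Amplitude slope" is read as a linear progression
from `A` in the first epoch to `A + slope` in the last — the simplest
testable reading. Sixty 500 ms epochs give a 30 s train; embedding tiles
the train `floor(baseline/train)` times into a baseline recording and trims
the excess (a 125 s baseline carries 120 s of signal with 5 s removed),
which reproduces the documented example and fixes the tiling-count reading.

`makeBaselineEeg()` emulates resting EEG as mixtures of four shared pink
(1/f) sources with smooth position-dependent weights plus 30 % independent
pink noise per channel, log-normal per-channel gain jitter (sd 0.1), and a
hemispheric electrode layout. What it captures: 1/f spectra, high but
imperfect inter-channel correlation (best-neighbour r ≈ 0.9), per-channel
gain spread. What it does not: non-stationarity, real artifact topographies
and temporal signatures, age- or state-dependent rhythms, volume-conduction
geometry from a head model. Passing benchmarks on this background therefore
demonstrates the pipeline's mechanics under controlled conditions, not
performance on any particular clinical population.

`injectArtifacts()` adds seeded blink transients (raised-cosine, 400 ms,
frontally weighted), EMG bursts (20–45 Hz, 300 ms), drift (smoothed random
walk) and a mains sinusoid, returning the added series so clean and
artifact-added variants share the identical underlying EEG — the property
the clean-vs-artifact comparison depends on.

## Benchmark problem sizes and noise level

The end-to-end protocol (`vepBenchmark()`) uses 16 clean + 16
artifact-added 30 s files at 250 Hz with 12 channels, processed through
line-noise removal, hard wavelet thresholding, a 0.1–35 Hz FIR filter,
[−100, 400] ms segmentation, 100 ms baseline correction and ±150 µV
rejection; the bad-channel benchmark uses 20 files of 39 channels (the
channel count the spectral criterion needs, as above). The benchmark's
baseline RMS is set to 3 µV rather than the 20 µV default of the
generator: with 60 trials and a single shared-noise-dominated ROI, that
level places the raw clean-condition component standard errors (~0.1 µV)
and the embedding distortion of the trial-averaged peaks (~1–1.5 %) at or
below the clean-condition values the benchmark design reports, so the
synthetic protocol probes the same regime — the evaluated criteria (clean
vs artifact gap, SE reduction, retention ordering) are all relative
comparisons and do not depend on the absolute scale. Evaluation averages
across all channels, mirroring the region-of-interest averaging of the
original design.

# Known limitations

* The wavelet stage's guarantees are background-relative (see above); on
  data whose "noise floor" is itself structured and sparse, the universal
  threshold can remove signal.
* The EDF reader supports equal-rate ordinary signals plus one annotations
  stream; mixed-rate files are rejected rather than resampled.
* Joint-probability rejection uses a histogram density; for very short
  epochs (< ~50 samples) its z-scores are coarse.
* The IIR order cap means extreme literal orders are not honoured; the cap
  and its reason are documented rather than silently absorbed.
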