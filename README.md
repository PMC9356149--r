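# erpflow

Automated preprocessing and quantification of event-related potentials
(ERPs) from continuous multichannel EEG, with a simulated-VEP benchmark for
validating the pipeline on data with known ground truth.

## Who this is for

Labs that record stimulus-locked EEG (visual/auditory evoked paradigms,
developmental and adult cohorts alike) and want a fully automated,
configuration-driven preprocessing chain — no per-file manual decisions —
plus quantitative reports that make batch quality auditable.

## What the pipeline does

For each file, in fixed order:

1. **Load** (EDF/EDF+ or a plain-text fixture format) and **select
   channels** by inclusion or exclusion.
2. **100 Hz lowpass**, then **line-noise removal** by multi-taper sinusoid
   regression: in sliding 4 s windows, the mains sinusoid (60 or 50 Hz
   ± 2 Hz) is estimated on Slepian tapers and subtracted only where
   Thomson's F-test is significant (p < 0.01) — removing the interference
   without touching neighbouring frequencies.
3. **Bad-channel detection** by four criteria (flatline > 5 s; mean
   log-power z above +3.5 or below −5 SD, run twice; line-noise/neural
   ratio z > 6; best-neighbour correlation < 0.8).
4. **Wavelet-threshold artifact correction** (undecimated coiflet-4,
   per-level universal threshold λ_j = s_j √(2 ln N), s_j from the
   coefficient MAD): supra-threshold coefficient content is removed as
   artifact. `soft` shrinks the excess, `hard` removes flagged
   coefficients entirely — more aggressive, suited to high-artifact data.
5. **ERP band filter** (zero-phase windowed-sinc FIR, or forward-backward
   Butterworth sections), e.g. 0.1–30 Hz.
6. **Segmentation** around event markers with timing-offset correction,
   **baseline correction**, optional **within-segment repair** (four
   per-segment channel statistics, |z| > 3, spherical-spline
   interpolation), and **segment rejection** by amplitude (±150 µV
   suggested) and/or joint probability (|z| > 3).
7. **Spherical-spline interpolation** of removed channels (Legendre kernel
   to order 7, stiffness m = 4), optional **re-referencing** (average or
   channel subset, with recovery of the prior online reference), and
   **condition splitting**.

Each batch writes a data-quality table (segments kept, percent good
channels, percent variance retained, …) and a pipeline-quality table
(pre/post correlations at and around the mains frequency and at ten probe
frequencies for the wavelet stage).

The ERP layer (`generateErps()`) builds per-file and grand-average
waveforms (± SE, 95 % CI) and the measure suite: windowed peak amplitudes
and latencies, global and local extrema, mean amplitudes, signed and
absolute area under the curve, and the 50 %-AUC latency, with window or
zero-crossing bounds.

The simulation layer builds a three-component visual evoked potential
(N1/P1/N2 Gaussians; 60 epochs × 500 ms = 30 s), embeds it into synthetic
1/f baseline EEG, injects seeded artifacts (blinks, EMG, drift, line), and
evaluates the pipeline against the known truth (`vepBenchmark()`,
`badChannelBenchmark()`).

## Worked example

```r
library(erpflow)

# simulate a 30 s VEP train and embed it into synthetic baseline EEG
sim  <- synthesizeEpochs(settings = simSettings(rate = 250))
base <- makeBaselineEeg(12, 30, 250, seed = 1, rms_uv = 3)
rec  <- embedInBaseline(sim$train, base)

# preprocess: lowpass, line noise, hard wavelet, ERP band, segment, reject
rec <- preCleanLowpass(rec)
rec <- removeLineNoise(rec)$rec
rec <- waveletClean(rec, waveletSettings(mode = "hard"))$rec
rec <- firBandpass(rec, filterSpec("fir_hamming", highpass = 0.1, lowpass = 35))
ep  <- segmentEvents(rec, "vep", segmentationSettings(window = c(-100, 400)))
ep  <- baselineCorrect(ep, c(-100, 0))
ep  <- rejectSegments(ep, rejectionPolicy("amplitude"))$epochs

# measure the recovered components against the simulated truth
erp   <- averageTrials(ep)
peaks <- findPeaks(erp, vepMeasureWindows(-100))
peaks$windows
#>    name polarity      peak latency
#> N1   N1      min -7.144204      68
#> P1   P1      max  3.958254      96
#> N2   N2      min -9.808822     136
truth <- findPeaks(averageTrials(sim$epochs), vepMeasureWindows(-100))
truth$windows$peak
#> [1] -8.296405  5.137692 -11.469349
```

The simulated train's trial-average N1 is −8.30 µV (the first-epoch
amplitude −7.5 µV deepened by the across-trial slope); the recovered N1 is
−7.14 µV. The shrink is the 35 Hz lowpass shaving the sharp peak plus
mild wavelet shrinkage at this deliberately quiet background — and it is
the *same* in clean and artifact-added conditions, which is exactly what
the benchmark quantifies (the clean-vs-artifact gap stays under 2 %).
Latencies are on the stimulus-locked axis (N1 at 68 ms ≙ 168 ms from
data start).

Batch processing is configuration-driven:

```r
cfg <- defaultRunConfig("path/to/files", "out", markers = "vep")
cfg$wavelet$mode <- "hard"
summary <- runPipeline(cfg)
summary$data_quality      # one row per file
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/erpflow.R make-fixtures --out demo --n-files 3 --seed 1
Rscript inst/cli/erpflow.R run --config out/run_config.json
Rscript inst/cli/erpflow.R add-sim-erp --input rest.json --out embedded.json
```

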