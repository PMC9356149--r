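Package: erpflow
Title: Automated Preprocessing and Quantification of Event-Related
    Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automated preprocessing of continuous multichannel EEG
    for event-related potential (ERP) analyses: multi-taper sinusoid
    regression for mains-line noise removal, composite bad-channel
    detection (flatline, spectral outlier, line-noise ratio, low
    correlation), artifact correction by stationary wavelet thresholding
    (soft or hard), zero-phase FIR/IIR band filtering, event segmentation
    with baseline correction, within-segment channel statistics and
    spherical-spline interpolation, amplitude and joint-probability
    segment rejection, re-referencing, and dual data/pipeline quality
    reports.  Includes an ERP quantification suite (peaks, latencies,
    mean amplitudes, area under the curve, 50% AUC latency) and a
    simulated visual-evoked-potential generator with artifact injection
    and an end-to-end evaluation harness for benchmarking the pipeline on
    data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
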