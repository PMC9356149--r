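# Ground-truth benchmark harnesses: planted-defect bad-channel benchmark and
# the clean vs artifact-added end-to-end protocol.

#' Planted-defect bad-channel benchmark
#'
#' Generates seeded synthetic files with known planted defects (flat,
#' high-power, line-contaminated and decorrelated channels), runs the
#' composite detector on each, and tallies recall and false-positive rate
#' over all channel decisions, mirroring the 20-file x 39-channel
#' optimization design.
#'
#' @param n_files number of files (default 20).
#' @param n_channels channels per file (default 39).
#' @param duration_s file length in seconds (default 30).
#' @param rate sampling rate (default 250).
#' @param master_seed seed from which per-file seeds derive.
#' @return list with \code{recall}, \code{false_positive_rate},
#'   \code{accuracy_pct}, \code{n_decisions} and the per-file truth/verdict
#'   tables.
#' @export
badChannelBenchmark <- function(n_files = 20, n_channels = 39,
                                duration_s = 30, rate = 250,
                                master_seed = 1) {
  tp <- fp <- fn <- tn <- 0L
  details <- vector("list", n_files)
  for (f in seq_len(n_files)) {
    seed <- master_seed * 1000L + f
    rec <- makeBaselineEeg(n_channels, duration_s, rate, seed = seed)
    data <- unname(eegData(rec))
    # plant 2-4 defects per file at distinct channels
    planted <- withSeed(seed + 1L, function() {
      k <- sample(2:4, 1)
      chans <- sample(n_channels, k)
      kinds <- sample(c("flat", "power", "line", "uncorr"), k,
                      replace = TRUE)
      n <- ncol(data)
      for (i in seq_len(k)) {
        ch <- chans[i]
        data[ch, ] <<- switch(kinds[i],
          flat = 0,
          power = 8 * data[ch, ],
          line = data[ch, ] + 60 * sin(2 * pi * 60 * (0:(n - 1)) / rate),
          uncorr = sd(data[ch, ]) * rnorm(n))
      }
      paste0("E", chans)
    })
    verdict <- detectBadChannels(newRecording(data, rate),
                                 line_freq = 60)$bad
    good <- setdiff(paste0("E", seq_len(n_channels)), planted)
    tp <- tp + length(intersect(verdict, planted))
    fn <- fn + length(setdiff(planted, verdict))
    fp <- fp + length(intersect(verdict, good))
    tn <- tn + length(setdiff(good, verdict))
    details[[f]] <- list(planted = planted, flagged = verdict)
  }
  list(recall = tp / (tp + fn),
       false_positive_rate = fp / (fp + tn),
       accuracy_pct = 100 * (tp + tn) / (tp + tn + fp + fn),
       n_decisions = tp + tn + fp + fn,
       details = details)
}

#' Clean vs artifact-added end-to-end benchmark
#'
#' Mirrors the simulated-VEP validation protocol: the default component
#' train is embedded into seeded synthetic baseline files, once clean and
#' once with injected artifacts sharing the identical underlying EEG; both
#' variants are processed through line-noise removal, (optionally) hard
#' wavelet thresholding, 0.1-35 Hz filtering, segmentation at [-100, 400]
#' ms, 100 ms baseline correction, and +/-150 uV rejection; component peaks
#' are measured against the simulated ground truth.
#'
#' @param n_files files per condition (default 16).
#' @param n_channels channels per file (default 12).
#' @param rate sampling rate (default 250).
#' @param rms_uv baseline RMS amplitude (default 3; see the methods
#'   vignette for the calibration of the benchmark's noise level).
#' @param master_seed seed from which all per-file seeds derive.
#' @param wavelet_mode \code{"hard"} or \code{"soft"}.
#' @return list with truth peaks, per-condition peak matrices, the
#'   unprocessed-embedding distortion, the clean-vs-artifact amplitude gap,
#'   per-condition SEs, and segment-retention counts.
#' @export
vepBenchmark <- function(n_files = 16, n_channels = 12, rate = 250,
                         rms_uv = 3, master_seed = 1,
                         wavelet_mode = "hard") {
  sim <- synthesizeEpochs(settings = simSettings(rate = rate))
  wins <- vepMeasureWindows(-100)
  truthW <- averageTrials(sim$epochs)
  truth <- findPeaks(truthW, wins)$windows$peak
  artSpecs <- list(artifactSpec("blink", 150, rate_per_min = 8),
                   artifactSpec("emg", 25, rate_per_min = 12),
                   artifactSpec("drift", 20),
                   artifactSpec("line", 5))
  segment <- function(rec) {
    ep <- segmentEvents(rec, "vep",
                        segmentationSettings(window = c(-100, 400)))
    baselineCorrect(ep, c(-100, 0))
  }
  process <- function(rec, wavelet = TRUE) {
    rec <- preCleanLowpass(rec)
    rec <- removeLineNoise(rec)$rec
    if (wavelet)
      rec <- waveletClean(rec, waveletSettings(mode = wavelet_mode))$rec
    rec <- firBandpass(rec, filterSpec("fir_hamming", highpass = 0.1,
                                       lowpass = 35))
    rejectSegments(segment(rec), rejectionPolicy("amplitude"))$epochs
  }
  peaks <- function(ep) {
    w <- averageTrials(ep)
    if (!length(w$values)) return(rep(NA_real_, 3))
    findPeaks(w, wins)$windows$peak
  }
  res <- lapply(seq_len(n_files), function(f) {
    seed <- master_seed * 10000L + f
    base <- makeBaselineEeg(n_channels, 30, rate, seed = seed,
                            rms_uv = rms_uv)
    art <- injectArtifacts(base, artSpecs, seed = seed + 5000L)$rec
    embClean <- embedInBaseline(sim$train, base)
    embArt <- embedInBaseline(sim$train, art)
    epClean <- process(embClean)
    epArt <- process(embArt)
    epArtRaw <- process(embArt, wavelet = FALSE)
    list(unproc = peaks(segment(embClean)),
         clean = peaks(epClean), art = peaks(epArt),
         artRaw = peaks(epArtRaw),
         rejectedClean = sum(keptTrials(epClean)) == 0,
         rejectedArt = sum(keptTrials(epArt)) == 0,
         keptArt = sum(keptTrials(epArt)),
         keptArtRaw = sum(keptTrials(epArtRaw)),
         nTrials = nTrials(epArt))
  })
  gather <- function(f) do.call(rbind, lapply(res, `[[`, f))
  up <- gather("unproc"); cl <- gather("clean")
  aw <- gather("art"); ar <- gather("artRaw")
  colnames(up) <- colnames(cl) <- colnames(aw) <- colnames(ar) <-
    names(wins)
  se <- function(m) apply(m, 2, stats::sd) / sqrt(nrow(m))
  list(truth = stats::setNames(truth, names(wins)),
       unprocessed = up, clean = cl, artifact = aw, artifact_raw = ar,
       embed_distortion_pct = 100 * abs(colMeans(up) / truth - 1),
       n1_gap_pct = 100 * abs(mean(aw[, 1]) - mean(cl[, 1])) /
         abs(mean(cl[, 1])),
       se_artifact = se(aw), se_artifact_raw = se(ar),
       participant_rejection_rate = 100 *
         mean(vapply(res, `[[`, FALSE, "rejectedArt")),
       kept_artifact = sum(vapply(res, `[[`, 0L, "keptArt")),
       kept_artifact_raw = sum(vapply(res, `[[`, 0L, "keptArtRaw")),
       total_trials = sum(vapply(res, `[[`, 0L, "nTrials")))
}
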