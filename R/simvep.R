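# Simulated visual-evoked-potential (VEP) synthesis, embedding into baseline
# EEG, synthetic artifact injection, and the ground-truth evaluation harness.

#' Specification of one simulated ERP component
#'
#' @param center_ms Gaussian peak centre, ms from epoch start (the defaults
#'   already include the 100 ms pre-stimulus shift).
#' @param width_ms component width in ms; the Gaussian sigma is width/6, so
#'   the waveform at centre +/- width/2 is exp(-4.5) of the peak.
#' @param amplitude_uv peak amplitude, uV.
#' @param amplitude_slope_uv amplitude change across the epoch train: the
#'   amplitude progresses linearly from \code{amplitude_uv} in the first
#'   epoch to \code{amplitude_uv + amplitude_slope_uv} in the last.
#' @return list of class \code{ComponentSpec}.
#' @export
componentSpec <- function(center_ms, width_ms, amplitude_uv,
                          amplitude_slope_uv = 0) {
  stopifnot(width_ms > 0)
  structure(list(center_ms = center_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv,
                 amplitude_slope_uv = amplitude_slope_uv),
            class = "ComponentSpec")
}

#' Default three-component VEP train (N1, P1, N2)
#'
#' N1: centre 170 ms, width 60, amplitude -7.5, slope -2.  P1: 200, 60,
#' +7.5, -2.  N2: 235, 100, -10, -3.
#' @return named list of [componentSpec()] objects.
#' @export
vepComponents <- function() {
  list(N1 = componentSpec(170, 60, -7.5, -2),
       P1 = componentSpec(200, 60, 7.5, -2),
       N2 = componentSpec(235, 100, -10, -3))
}

#' Simulation settings
#'
#' @param n_epochs number of simulated trials (default 60).
#' @param epoch_ms epoch length in ms (default 500; defaults give a 30 s
#'   train).
#' @param rate sampling rate, Hz (default 1000).
#' @param baseline_offset_ms position of the stimulus marker within each
#'   epoch (default 100; component centres are pre-shifted accordingly).
#' @param rejection_uv amplitude-rejection bound used in evaluation
#'   (default 150).
#' @return list of class \code{SimSettings}.
#' @export
simSettings <- function(n_epochs = 60, epoch_ms = 500, rate = 1000,
                        baseline_offset_ms = 100, rejection_uv = 150) {
  stopifnot(n_epochs >= 1)
  structure(list(n_epochs = n_epochs, epoch_ms = epoch_ms, rate = rate,
                 baseline_offset_ms = baseline_offset_ms,
                 rejection_uv = rejection_uv),
            class = "SimSettings")
}

#' Waveform of a single simulated component
#'
#' Gaussian peak \code{amplitude exp(-(t - center)^2 / (2 sigma^2))} with
#' \code{sigma = width/6}, sampled on the epoch grid.
#'
#' @param spec a [componentSpec()].
#' @param rate sampling rate, Hz.
#' @param epoch_ms epoch length, ms.
#' @param amplitude override amplitude (used for the per-epoch slope).
#' @return numeric waveform, uV.
#' @export
componentWaveform <- function(spec, rate, epoch_ms, amplitude = NULL) {
  n <- round(epoch_ms * rate / 1000)
  t <- (seq_len(n) - 1) * 1000 / rate
  a <- if (is.null(amplitude)) spec$amplitude_uv else amplitude
  sigma <- spec$width_ms / 6
  a * exp(-(t - spec$center_ms)^2 / (2 * sigma^2))
}

#' Synthesize the simulated epoch train
#'
#' Per epoch e of N, each component's amplitude is
#' \code{A + slope (e-1)/(N-1)}; the epoch is the sum of component
#' waveforms; the continuous train is the concatenation with a stimulus
#' marker \code{baseline_offset_ms} into each epoch.
#'
#' @param specs list of [componentSpec()] (default [vepComponents()]).
#' @param settings a [simSettings()].
#' @return list with \code{epochs} (an [EpochSet-class]) and \code{train}
#'   (a one-channel [EEGRecording-class] with the markers).
#' @export
synthesizeEpochs <- function(specs = vepComponents(),
                             settings = simSettings()) {
  stopifnot(length(specs) > 0)
  n <- round(settings$epoch_ms * settings$rate / 1000)
  for (s in specs)
    if (s$center_ms + s$width_ms / 2 > settings$epoch_ms)
      stop("spec error: component extends beyond the epoch")
  N <- settings$n_epochs
  arr <- array(0, dim = c(N, 1, n))
  for (e in seq_len(N)) {
    frac <- if (N > 1) (e - 1) / (N - 1) else 0
    w <- numeric(n)
    for (s in specs)
      w <- w + componentWaveform(s, settings$rate, settings$epoch_ms,
                                 s$amplitude_uv + s$amplitude_slope_uv * frac)
    arr[e, 1, ] <- w
  }
  off <- round(settings$baseline_offset_ms * settings$rate / 1000)
  time <- ((seq_len(n) - 1) - off) * 1000 / settings$rate
  epochs <- new("EpochSet", data = arr, time = time, labels = "sim",
                rate = settings$rate, conditions = rep("vep", N),
                kept = rep(TRUE, N), interpolated = rep(list(character(0)), N),
                notes = character(0))
  trainSig <- matrix(aperm(arr, c(3, 1, 2)), nrow = 1)
  events <- data.frame(name = "vep",
                       onset = (seq_len(N) - 1) * n + off)
  train <- newRecording(trainSig, rate = settings$rate, labels = "sim",
                        events = events)
  list(epochs = epochs, train = train)
}

# run body with a private RNG stream, restoring the caller's state
withSeed <- function(seed, body) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  body()
}

#' Unit-variance 1/f (pink) Gaussian noise
#'
#' Spectrally shaped white noise with amplitude proportional to
#' \code{1/sqrt(f)}, the canonical stand-in for ongoing EEG background.
#' Uses the current RNG stream.
#'
#' @param n number of samples.
#' @return numeric vector with mean 0 and SD 1.
#' @export
pinkNoise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# roughly uniform electrode layout on the upper unit hemisphere
hemisphereMontage <- function(n) {
  i <- seq_len(n)
  phi <- (1 + sqrt(5)) / 2
  z <- (i - 0.5) / n                      # upper hemisphere
  r <- sqrt(1 - z^2)
  th <- 2 * pi * i / phi
  data.frame(label = paste0("E", i), x = r * cos(th), y = r * sin(th), z = z)
}

#' Generate synthetic multichannel baseline EEG
#'
#' Channels are mixtures of shared 1/f (pink-noise) sources with smooth
#' position-dependent weights plus a small independent pink-noise component,
#' giving realistic inter-channel correlations; amplitudes are scaled to a
#' typical resting-EEG RMS.
#'
#' @param n_channels number of channels.
#' @param duration_s length in seconds.
#' @param rate sampling rate, Hz.
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @param rms_uv typical per-channel RMS amplitude (default 20 uV); actual
#'   channel gains are jittered log-normally (sd 0.1 in log) around it, as
#'   on a real cap.
#' @param indep_frac amplitude fraction of the channel-independent noise
#'   (default 0.3, yielding best-neighbour correlations near 0.9).
#' @return an [EEGRecording-class] with a hemispheric montage.
#' @export
makeBaselineEeg <- function(n_channels, duration_s, rate, seed,
                            rms_uv = 20, indep_frac = 0.3) {
  withSeed(seed, function() {
    n <- round(duration_s * rate)
    mont <- hemisphereMontage(n_channels)
    src <- rbind(pinkNoise(n), pinkNoise(n), pinkNoise(n), pinkNoise(n))
    w <- cbind(1, mont$x, mont$y, mont$z)       # smooth scalp patterns
    w <- w / sqrt(rowSums(w^2))
    data <- w %*% src
    for (ch in seq_len(n_channels))
      data[ch, ] <- data[ch, ] + indep_frac * pinkNoise(n)
    gains <- rms_uv * exp(stats::rnorm(n_channels, 0, 0.1))
    data <- data / apply(data, 1, stats::sd) * gains
    newRecording(data, rate = rate, montage = mont,
                 labels = mont$label, reference = "Cz")
  })
}

#' Embed the simulated train into baseline EEG
#'
#' The train is tiled \code{floor(baseline/train)} times and added to every
#' selected channel; excess baseline samples are trimmed from the end, and
#' the train's markers are inserted per tile.
#'
#' @param train one-channel [EEGRecording-class] from [synthesizeEpochs()].
#' @param baseline an [EEGRecording-class]; must be at least one train long
#'   and at the same rate (resample the train first otherwise).
#' @param channels channel names receiving the train (default all).
#' @return the embedded [EEGRecording-class] (duration = tiles x train).
#' @export
embedInBaseline <- function(train, baseline, channels = NULL) {
  if (abs(train@rate - baseline@rate) > 1e-9)
    stop("rate mismatch: resample the train to the baseline rate first")
  nt <- ncol(train@data)
  nb <- ncol(baseline@data)
  tiles <- floor(nb / nt)
  if (tiles < 1) stop("length error: baseline shorter than one train")
  keep <- tiles * nt
  out <- baseline
  out@data <- out@data[, seq_len(keep), drop = FALSE]
  sig <- rep(as.numeric(train@data[1, ]), tiles)
  chans <- if (is.null(channels)) out@labels else channels
  unknown <- setdiff(chans, out@labels)
  if (length(unknown))
    stop("selection error: unknown channel(s): ", paste(unknown, collapse = ", "))
  idx <- match(chans, out@labels)
  out@data[idx, ] <- sweep(out@data[idx, , drop = FALSE], 2, sig, "+")
  ev <- do.call(rbind, lapply(seq_len(tiles) - 1L, function(k) {
    e <- train@events
    e$onset <- e$onset + k * nt
    e
  }))
  out@events <- normalizeEvents(ev)
  out <- addProvenance(out, "embed_sim_erp",
                       list(tiles = tiles, trimmed_s = (nb - keep) / out@rate))
  validObject(out)
  out
}

#' Artifact class specification
#'
#' @param kind \code{"blink"}, \code{"emg"}, \code{"drift"} or \code{"line"}.
#' @param amplitude amplitude scale in uV (peak for blinks/line, RMS for
#'   EMG/drift).
#' @param rate_per_min event rate for transient kinds (blink, emg).
#' @return list of class \code{ArtifactSpec}.
#' @export
artifactSpec <- function(kind = c("blink", "emg", "drift", "line"),
                         amplitude, rate_per_min = 10) {
  kind <- match.arg(kind)
  structure(list(kind = kind, amplitude = amplitude,
                 rate_per_min = rate_per_min), class = "ArtifactSpec")
}

#' Inject synthetic artifacts into a recording
#'
#' Adds seeded blink transients (raised-cosine, 400 ms, frontally weighted),
#' EMG bursts (20-45 Hz band-limited noise, 300 ms, random channel
#' weighting), low-frequency drift (smoothed random walk) and/or a mains
#' sinusoid.  The added series is returned so that the clean and
#' artifact-added variants share the identical underlying signal.
#'
#' @param rec an [EEGRecording-class].
#' @param specs list of [artifactSpec()] objects.
#' @param seed RNG seed (caller's RNG untouched).
#' @return list with \code{rec} (artifact-added) and \code{artifact} (the
#'   added series as an [EEGRecording-class]).
#' @export
injectArtifacts <- function(rec, specs, seed) {
  nch <- nrow(rec@data); n <- ncol(rec@data); rate <- rec@rate
  art <- matrix(0, nch, n)
  frontW <- if (nrow(rec@montage)) pmax(rec@montage$y, 0)^2 + 0.05
            else rep(1, nch)
  frontW <- frontW / max(frontW)
  withSeed(seed, function() {
    for (sp in specs) {
      if (sp$amplitude == 0) next
      if (sp$kind == "blink") {
        len <- round(0.4 * rate)
        shape <- sp$amplitude * (1 - cos(2 * pi * seq_len(len) / len)) / 2
        k <- stats::rpois(1, sp$rate_per_min * n / rate / 60)
        if (k > 0) for (s in sort(stats::runif(k, 0, n - len))) {
          i <- floor(s)
          art[, (i + 1):(i + len)] <<- art[, (i + 1):(i + len)] +
            outer(frontW, shape)
        }
      } else if (sp$kind == "emg") {
        len <- round(0.3 * rate)
        k <- stats::rpois(1, sp$rate_per_min * n / rate / 60)
        if (k > 0) for (s in sort(stats::runif(k, 0, n - len))) {
          i <- floor(s)
          burst <- bandNoise(len, rate, 20, min(45, rate / 2 * 0.9)) *
            sp$amplitude
          taper <- sin(pi * seq_len(len) / len)^2
          w <- stats::runif(nch)^2
          art[, (i + 1):(i + len)] <<- art[, (i + 1):(i + len)] +
            outer(w, burst * taper)
        }
      } else if (sp$kind == "drift") {
        for (ch in seq_len(nch)) {
          rw <- cumsum(stats::rnorm(n))
          rw <- stats::filter(rw, rep(1 / round(rate), round(rate)),
                              sides = 2, circular = TRUE)
          rw <- as.numeric(rw)
          art[ch, ] <<- art[ch, ] + rw / stats::sd(rw) * sp$amplitude
        }
      } else if (sp$kind == "line") {
        ph <- stats::runif(1, 0, 2 * pi)
        art <<- art + matrix(sp$amplitude *
          sin(2 * pi * 60 * (seq_len(n) - 1) / rate + ph),
          nch, n, byrow = TRUE)
      }
    }
    NULL
  })
  out <- rec
  out@data <- rec@data + art
  rownames(out@data) <- out@labels
  artRec <- rec
  artRec@data <- art
  rownames(artRec@data) <- artRec@labels
  list(rec = addProvenance(out, "inject_artifacts", list(seed = seed)),
       artifact = artRec)
}

bandNoise <- function(n, rate, f1, f2) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  sp[f < f1 | f > f2] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Evaluate processed epoch sets against the simulated ground truth
#'
#' Computes the evaluation criteria of the benchmarking protocol: files
#' fully rejected / total; per-window peak (and peak-to-peak) distortion of
#' the trial-average against the simulated truth; the mean clean-vs-artifact
#' amplitude difference; the across-file SE of component amplitudes; and
#' segment retention under the amplitude bound.
#'
#' @param processed list of [EpochSet-class], one per file (clean
#'   condition).
#' @param truth \code{ERPWaveform} of the simulated train's trial average.
#' @param settings a [simSettings()].
#' @param windows measurement windows (default [vepMeasureWindows()]).
#' @param processedArtifact optional list of artifact-added counterparts.
#' @return list of class \code{EvalReport}.
#' @export
evaluatePipeline <- function(processed, truth, settings = simSettings(),
                             windows = vepMeasureWindows(),
                             processedArtifact = NULL) {
  if (!length(processed)) stop("report error: no processed files")
  truthPeaks <- findPeaks(truth, windows)$windows$peak
  measure <- function(sets) {
    peaks <- t(vapply(sets, function(ep) {
      w <- averageTrials(ep)
      if (!length(w$values)) return(rep(NA_real_, length(windows)))
      findPeaks(w, windows)$windows$peak
    }, numeric(length(windows))))
    colnames(peaks) <- names(windows)
    peaks
  }
  peaks <- measure(processed)
  rejected <- vapply(processed, function(ep) sum(ep@kept) == 0, FALSE)
  distort <- sweep(peaks, 2, truthPeaks, "-")
  distortPct <- 100 * abs(sweep(distort, 2, abs(truthPeaks), "/"))
  se <- apply(peaks, 2, function(p) stats::sd(p, na.rm = TRUE) /
                sqrt(sum(is.finite(p))))
  kept <- vapply(processed, function(ep) sum(ep@kept), 0L)
  total <- vapply(processed, nTrials, 0L)
  cleanVsArt <- NULL
  if (!is.null(processedArtifact)) {
    pa <- measure(processedArtifact)
    cleanVsArt <- mean(abs(peaks - pa), na.rm = TRUE)
  }
  structure(list(
    participant_rejection_rate = 100 * mean(rejected),
    peaks = peaks,
    truth_peaks = stats::setNames(truthPeaks, names(windows)),
    distortion_uv = colMeans(distort, na.rm = TRUE),
    distortion_pct = colMeans(distortPct, na.rm = TRUE),
    clean_vs_artifact_uv = cleanVsArt,
    se = se,
    segments_retained = sum(kept),
    segments_total = sum(total),
    retention_pct = 100 * sum(kept) / sum(total)),
    class = "EvalReport")
}
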