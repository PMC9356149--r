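#' Settings for composite bad-channel detection
#'
#' Thresholds follow the empirically optimized defaults of the pipeline:
#' flatline longer than 5 s; spectral z outside (-5, +3.5) run twice;
#' line-noise/neural ratio z above 6; best-neighbour correlation below 0.8.
#'
#' @param flatline_max_s longest tolerated flat run, seconds (default 5).
#' @param spec_band frequency band (Hz) for mean log-power (default c(1,100),
#'   matching the 100 Hz pre-clean lowpass).
#' @param spec_low_sd,spec_high_sd asymmetric z thresholds for spectral
#'   outliers (defaults -5 and +3.5; the lenient low side protects channels
#'   near the online reference, which share variance with it).
#' @param spec_passes number of spectral passes (default 2: flag, drop,
#'   re-estimate, flag again; union reported).
#' @param line_ratio_sd robust-z threshold on the line/neural power ratio
#'   (default 6).
#' @param corr_min minimum acceptable mean best-neighbour correlation
#'   (default 0.8).
#' @param corr_window_s correlation window length in seconds (default 1).
#' @return list of class \code{BadChannelSettings}.
#' @export
badChannelSettings <- function(flatline_max_s = 5, spec_band = c(1, 100),
                               spec_low_sd = -5, spec_high_sd = 3.5,
                               spec_passes = 2, line_ratio_sd = 6,
                               corr_min = 0.8, corr_window_s = 1) {
  stopifnot(spec_low_sd < 0, spec_high_sd > 0, corr_min > 0, corr_min < 1)
  structure(list(flatline_max_s = flatline_max_s, spec_band = spec_band,
                 spec_low_sd = spec_low_sd, spec_high_sd = spec_high_sd,
                 spec_passes = spec_passes, line_ratio_sd = line_ratio_sd,
                 corr_min = corr_min, corr_window_s = corr_window_s),
            class = "BadChannelSettings")
}

#' Detect a prolonged flatline in one channel
#'
#' TRUE iff a contiguous run with absolute first difference below 1e-8 uV
#' lasts strictly longer than \code{flatline_max_s}.
#'
#' @param x one channel's samples.
#' @param rate sampling rate, Hz.
#' @param flatline_max_s threshold in seconds (default 5).
#' @return logical.
#' @export
detectFlatline <- function(x, rate, flatline_max_s = 5) {
  flat <- abs(diff(x)) < 1e-8
  if (!any(flat)) return(FALSE)
  r <- rle(flat)
  runs <- r$lengths[r$values]
  # a run of m flat differences spans m+1 samples, i.e. m/rate seconds of
  # zero slope beyond the first sample
  max(runs) / rate > flatline_max_s
}

# Welch mean power spectral density, 1-s hamming windows, 50% overlap
welchPsd <- function(x, rate, window_s = 1) {
  n <- length(x)
  win <- max(8L, round(window_s * rate))
  if (win > n) win <- n
  step <- max(1L, win %/% 2L)
  h <- 0.54 - 0.46 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  starts <- seq(1, n - win + 1, by = step)
  acc <- numeric(win %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + win - 1)]
    seg <- (seg - mean(seg)) * h
    sp <- Mod(stats::fft(seg))^2 / (sum(h^2) * rate)
    acc <- acc + sp[1:(win %/% 2 + 1)]
  }
  list(freq = (0:(win %/% 2)) * rate / win, psd = acc / length(starts))
}

channelLogPower <- function(rec, band) {
  vapply(seq_len(nrow(rec@data)), function(i) {
    p <- welchPsd(rec@data[i, ], rec@rate)
    sel <- p$freq >= band[1] & p$freq <= band[2]
    mean(log10(pmax(p$psd[sel], 1e-300)))
  }, 0)
}

zScore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Detect spectral-outlier channels
#'
#' Per channel, the mean log10 Welch power over \code{spec_band}; channels
#' are flagged when the across-channel z-score exceeds \code{spec_high_sd}
#' or falls below \code{spec_low_sd}.  The pass is run twice: flagged
#' channels are removed, z-scores recomputed among the remainder, and the
#' union of both passes is returned.
#'
#' @param rec an [EEGRecording-class] (at least 2 channels).
#' @param settings a [badChannelSettings()].
#' @return character vector of flagged channel labels.
#' @export
detectSpectralOutliers <- function(rec, settings = badChannelSettings()) {
  if (nrow(rec@data) < 2) stop("detection error: need at least 2 channels")
  lp <- channelLogPower(rec, settings$spec_band)
  names(lp) <- rec@labels
  flagged <- character(0)
  active <- rec@labels
  for (pass in seq_len(settings$spec_passes)) {
    z <- zScore(lp[active])
    bad <- active[z > settings$spec_high_sd | z < settings$spec_low_sd]
    flagged <- union(flagged, bad)
    active <- setdiff(active, bad)
    if (!length(bad) || length(active) < 2) break
  }
  flagged
}

#' Detect channels dominated by line noise
#'
#' Per channel, the log ratio of power within \code{line_freq +/- 1 Hz} to
#' power in \code{spec_band} excluding that interval; channels are flagged
#' when the robust z (median / 1.4826 MAD) across channels exceeds
#' \code{line_ratio_sd}.
#'
#' @param rec an [EEGRecording-class].
#' @param settings a [badChannelSettings()].
#' @param line_freq mains frequency in Hz.
#' @return character vector of flagged channel labels.
#' @export
detectLineRatioOutliers <- function(rec, settings = badChannelSettings(),
                                    line_freq = 60) {
  if (line_freq >= rec@rate / 2) stop("frequency error: line_freq above Nyquist")
  band <- settings$spec_band
  ratio <- vapply(seq_len(nrow(rec@data)), function(i) {
    p <- welchPsd(rec@data[i, ], rec@rate)
    inLine <- p$freq >= line_freq - 1 & p$freq <= line_freq + 1
    inBand <- p$freq >= band[1] & p$freq <= band[2] & !inLine
    log10(pmax(sum(p$psd[inLine]), 1e-300) /
          pmax(sum(p$psd[inBand]), 1e-300))
  }, 0)
  med <- stats::median(ratio)
  madv <- stats::mad(ratio)
  if (madv < 1e-12) return(character(0))
  z <- (ratio - med) / madv
  rec@labels[z > settings$line_ratio_sd]
}

#' Detect channels poorly correlated with all others
#'
#' The recording is split into \code{corr_window_s} windows; per window and
#' channel the maximum absolute product-moment correlation with any other
#' channel is taken, and a channel is flagged iff the mean over windows of
#' this best correlation falls below \code{corr_min}.
#'
#' @param rec an [EEGRecording-class] (at least 3 channels).
#' @param settings a [badChannelSettings()].
#' @return character vector of flagged channel labels.
#' @export
detectLowCorrelation <- function(rec, settings = badChannelSettings()) {
  nc <- nrow(rec@data)
  if (nc < 3) stop("detection error: need at least 3 channels")
  win <- max(2L, round(settings$corr_window_s * rec@rate))
  n <- ncol(rec@data)
  starts <- seq(1, n - win + 1, by = win)
  best <- matrix(NA_real_, length(starts), nc)
  for (k in seq_along(starts)) {
    seg <- t(rec@data[, starts[k]:(starts[k] + win - 1), drop = FALSE])
    sds <- apply(seg, 2, stats::sd)
    cc <- suppressWarnings(abs(stats::cor(seg)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 0
    best[k, ] <- apply(cc, 2, max)
    best[k, sds < 1e-12] <- 0                  # flat segment correlates with nothing
  }
  mb <- colMeans(best)
  rec@labels[mb < settings$corr_min]
}

#' Composite bad-channel detection
#'
#' Runs, in order, flatline detection, the two-pass spectral-outlier
#' criterion, the line-noise-ratio criterion, and the low-correlation
#' criterion, each applied to channels surviving the previous criteria.
#' The union is reported with the triggering criterion per channel.
#'
#' @param rec an [EEGRecording-class] (at least 3 channels).
#' @param settings a [badChannelSettings()].
#' @param line_freq mains frequency in Hz (default 60).
#' @return list of class \code{BadChannelReport} with elements
#'   \code{bad} (labels), \code{criteria} (named list, criterion names per
#'   bad channel), \code{good} (labels) and \code{percent_good}.
#' @export
detectBadChannels <- function(rec, settings = badChannelSettings(),
                              line_freq = 60) {
  criteria <- list()
  flagAs <- function(labels, why) {
    for (l in labels) criteria[[l]] <<- union(criteria[[l]], why)
  }
  flat <- rec@labels[vapply(seq_len(nrow(rec@data)), function(i)
    detectFlatline(rec@data[i, ], rec@rate, settings$flatline_max_s), FALSE)]
  flagAs(flat, "flatline")
  surv <- setdiff(rec@labels, flat)

  sub <- function(labels) selectChannels(rec, "include", labels)
  if (length(surv) >= 2) {
    spec <- detectSpectralOutliers(sub(surv), settings)
    flagAs(spec, "spectrum")
    surv <- setdiff(surv, spec)
  }
  if (length(surv) >= 2) {
    lr <- detectLineRatioOutliers(sub(surv), settings, line_freq)
    flagAs(lr, "line_ratio")
    surv <- setdiff(surv, lr)
  }
  if (length(surv) >= 3) {
    lc <- detectLowCorrelation(sub(surv), settings)
    flagAs(lc, "correlation")
    surv <- setdiff(surv, lc)
  }
  bad <- setdiff(rec@labels, surv)
  structure(list(bad = bad, criteria = criteria, good = surv,
                 percent_good = 100 * length(surv) / length(rec@labels)),
            class = "BadChannelReport")
}
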