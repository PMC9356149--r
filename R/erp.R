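#' Measurement window for an ERP component
#'
#' @param start_ms,end_ms window bounds in ms (inclusive at both ends after
#'   rounding to the sample grid).
#' @param polarity \code{"max"} (positive component) or \code{"min"}
#'   (negative component).
#' @param name optional component label.
#' @return list of class \code{MeasureWindow}.
#' @export
measureWindow <- function(start_ms, end_ms, polarity = c("max", "min"),
                          name = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(start_ms < end_ms)
  structure(list(start_ms = start_ms, end_ms = end_ms, polarity = polarity,
                 name = name), class = "MeasureWindow")
}

#' Default component windows for the simulated visual evoked potential
#'
#' N1 150-190 ms (min), P1 180-220 ms (max), N2 215-255 ms (min), stated on
#' the simulated-data axis (0 = data start, components centred at 170, 200
#' and 235 ms).  When measuring stimulus-locked epochs whose time axis is
#' relative to the marker (which sits 100 ms into each simulated epoch),
#' use \code{offset_ms = -100} to express the same windows on that axis.
#'
#' @param offset_ms shift applied to both window edges (default 0).
#' @return named list of [measureWindow()] objects.
#' @export
vepMeasureWindows <- function(offset_ms = 0) {
  list(N1 = measureWindow(150 + offset_ms, 190 + offset_ms, "min", "N1"),
       P1 = measureWindow(180 + offset_ms, 220 + offset_ms, "max", "P1"),
       N2 = measureWindow(215 + offset_ms, 255 + offset_ms, "min", "N2"))
}

#' Average kept trials into an ERP waveform
#'
#' Mean across kept trials, then across the selected channels.
#'
#' @param epochs an [EpochSet-class].
#' @param channels channel names to include (default all).
#' @param exclude channel names to exclude (e.g. channels marked bad).
#' @return list of class \code{ERPWaveform} with \code{values}, \code{time},
#'   \code{n_trials}; empty values with a note if no trials are kept.
#' @export
averageTrials <- function(epochs, channels = NULL, exclude = character(0)) {
  labels <- epochs@labels
  sel <- if (is.null(channels)) labels else intersect(labels, channels)
  sel <- setdiff(sel, exclude)
  if (!length(sel)) stop("no channels selected")
  keep <- which(epochs@kept)
  if (!length(keep))
    return(structure(list(values = numeric(0), time = epochs@time,
                          n_trials = 0L, note = "zero kept trials"),
                     class = "ERPWaveform"))
  chIdx <- match(sel, labels)
  avg <- apply(epochs@data[keep, chIdx, , drop = FALSE], 3, mean)
  structure(list(values = avg, time = epochs@time,
                 n_trials = length(keep), note = NULL),
            class = "ERPWaveform")
}

#' Grand average across subject waveforms
#'
#' @param waveforms list of \code{ERPWaveform} objects on the same time
#'   axis.
#' @return list with \code{time}, \code{mean}, \code{se} (sample SD /
#'   sqrt(n)) and \code{ci_low}/\code{ci_high} (mean +/- 1.96 SE) per
#'   timepoint, and \code{n}.
#' @export
grandAverage <- function(waveforms) {
  stopifnot(length(waveforms) >= 2)
  t0 <- waveforms[[1]]$time
  for (w in waveforms)
    if (length(w$time) != length(t0) || max(abs(w$time - t0)) > 1e-9)
      stop("alignment error: waveforms on different time axes")
  mat <- do.call(rbind, lapply(waveforms, `[[`, "values"))
  mu <- colMeans(mat)
  se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  list(time = t0, mean = mu, se = se,
       ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se, n = nrow(mat))
}

windowIdx <- function(time, start_ms, end_ms) {
  idx <- which(time >= start_ms - 1e-9 & time <= end_ms + 1e-9)
  if (!length(idx)) stop("window error: window outside time axis")
  idx
}

#' Peak amplitudes and latencies
#'
#' Per measurement window, the extremum of the requested polarity and its
#' latency (earliest sample wins ties); plus the global maximum/minimum with
#' latencies and the full lists of local maxima and minima.
#'
#' @param erp an \code{ERPWaveform}.
#' @param windows list of [measureWindow()] objects.
#' @return list with \code{windows} (data.frame name/peak/latency),
#'   \code{global} and \code{local} extrema.
#' @export
findPeaks <- function(erp, windows = list()) {
  v <- erp$values; tm <- erp$time
  rows <- lapply(windows, function(w) {
    idx <- windowIdx(tm, w$start_ms, w$end_ms)
    i <- if (w$polarity == "max") idx[which.max(v[idx])]
         else idx[which.min(v[idx])]
    data.frame(name = if (is.null(w$name)) NA_character_ else w$name,
               polarity = w$polarity, peak = v[i], latency = tm[i])
  })
  sgn <- diff(sign(diff(v)))
  locMax <- which(sgn < 0) + 1
  locMin <- which(sgn > 0) + 1
  list(windows = if (length(rows)) do.call(rbind, rows) else NULL,
       global = data.frame(
         what = c("max", "min"),
         peak = c(max(v), min(v)),
         latency = c(tm[which.max(v)], tm[which.min(v)])),
       local = list(
         maxima = data.frame(peak = v[locMax], latency = tm[locMax]),
         minima = data.frame(peak = v[locMin], latency = tm[locMin])))
}

#' Latency windows bounded by zero crossings
#'
#' Boundaries are the axis start, each sign change (assigned to the first
#' sample after the change; samples exactly zero are boundaries), and the
#' axis end.  The windows partition the axis.
#'
#' @param erp an \code{ERPWaveform} (post-stimulus portion is used when
#'   \code{post_only}).
#' @param post_only restrict to time >= 0 (default TRUE).
#' @return data.frame with \code{start_ms}, \code{end_ms}.
#' @export
zeroCrossingWindows <- function(erp, post_only = TRUE) {
  sel <- if (post_only) erp$time >= 0 else rep(TRUE, length(erp$time))
  v <- erp$values[sel]; tm <- erp$time[sel]
  n <- length(v)
  bounds <- 1L
  for (i in 2:n) {
    if (v[i] == 0 || (v[i - 1] != 0 && sign(v[i]) != sign(v[i - 1])))
      bounds <- c(bounds, i)
  }
  bounds <- unique(c(bounds, n))
  data.frame(start_ms = tm[bounds[-length(bounds)]],
             end_ms = tm[bounds[-1]])
}

#' Mean amplitude over a latency window
#'
#' @param erp an \code{ERPWaveform}.
#' @param window numeric \code{c(start_ms, end_ms)} or a [measureWindow()].
#' @return mean of the samples in \code{[start, end]} inclusive, in uV.
#' @export
meanAmplitude <- function(erp, window) {
  if (inherits(window, "MeasureWindow"))
    window <- c(window$start_ms, window$end_ms)
  mean(erp$values[windowIdx(erp$time, window[1], window[2])])
}

#' Area-under-the-curve measures
#'
#' Trapezoidal signed AUC (uV ms) over the window; global AUC of the
#' absolute waveform over the whole post-stimulus axis; 50% AUC and the
#' first latency at which the cumulative absolute area within the window
#' reaches half the window total.
#'
#' @param erp an \code{ERPWaveform}.
#' @param window numeric \code{c(start_ms, end_ms)}, a [measureWindow()],
#'   or \code{NULL} to use the whole post-stimulus axis.
#' @return list with \code{auc}, \code{auc50}, \code{auc50_latency} (NA when
#'   the window area is zero) and \code{global_abs_auc}.
#' @export
areaMeasures <- function(erp, window = NULL) {
  if (inherits(window, "MeasureWindow"))
    window <- c(window$start_ms, window$end_ms)
  post <- erp$time >= 0
  trapz <- function(x, y) if (length(x) < 2) 0 else
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  globalAbs <- trapz(erp$time[post], abs(erp$values[post]))
  if (is.null(window)) window <- range(erp$time[post])
  idx <- windowIdx(erp$time, window[1], window[2])
  x <- erp$time[idx]; y <- erp$values[idx]
  auc <- trapz(x, y)
  absInc <- c(0, diff(x) * (abs(head(y, -1)) + abs(y[-1])) / 2)
  cum <- cumsum(absInc)
  total <- cum[length(cum)]
  if (total <= 0) {
    lat50 <- NA_real_
  } else {
    lat50 <- x[which(cum >= total / 2)[1]]
  }
  list(auc = auc, auc50 = total / 2, auc50_latency = lat50,
       global_abs_auc = globalAbs)
}

#' Peak-to-peak amplitudes between consecutive components
#'
#' \code{value_k = peak_k - peak_(k-1)} (current minus prior), so a
#' negative-then-positive pair yields a positive difference.
#'
#' @param peaks numeric vector of component peak amplitudes ordered by
#'   latency, optionally named.
#' @return named numeric vector of consecutive differences.
#' @export
peakToPeak <- function(peaks) {
  stopifnot(length(peaks) >= 2)
  out <- diff(peaks)
  nm <- names(peaks)
  if (!is.null(nm))
    names(out) <- paste0(nm[-length(nm)], "-", nm[-1])
  out
}

#' @importFrom utils head
NULL
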