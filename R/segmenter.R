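#' Segmentation settings
#'
#' @param window \code{c(start_ms, end_ms)} relative to stimulus onset; the
#'   epoch covers the half-open sample range.
#' @param timing_offset_ms stimulus-presentation timing offset added to both
#'   edges (may be 0).
#' @param baseline_window \code{c(b0_ms, b1_ms)} with \code{b1 <= 0}, within
#'   the pre-stimulus part of \code{window}.
#' @return list of class \code{SegmentationSettings}.
#' @export
segmentationSettings <- function(window = c(-100, 400), timing_offset_ms = 0,
                                 baseline_window = c(window[1], 0)) {
  stopifnot(window[1] < window[2], baseline_window[2] <= 0,
            baseline_window[1] >= window[1])
  structure(list(window = window, timing_offset_ms = timing_offset_ms,
                 baseline_window = baseline_window),
            class = "SegmentationSettings")
}

#' Segment-rejection policy
#'
#' @param criteria \code{"amplitude"}, \code{"jointprob"} or \code{"both"}.
#' @param amp_low,amp_high amplitude bounds in microvolts (suggested
#'   -150/150 for child through adult data, -200/200 for infants).
#' @param jp_sd joint-probability z cutoff (default 3).
#' @param roi optional channel subset to which evaluation is restricted.
#' @return list of class \code{RejectionPolicy}.
#' @export
rejectionPolicy <- function(criteria = c("amplitude", "jointprob", "both"),
                            amp_low = -150, amp_high = 150, jp_sd = 3,
                            roi = NULL) {
  criteria <- match.arg(criteria)
  stopifnot(amp_low < amp_high, jp_sd > 0)
  structure(list(criteria = criteria, amp_low = amp_low,
                 amp_high = amp_high, jp_sd = jp_sd, roi = roi),
            class = "RejectionPolicy")
}

#' Per-segment channel statistics settings
#'
#' @param z_cut z-score cutoff (default 3).
#' @param metrics which of the four segment statistics to evaluate.
#' @return list of class \code{FasterSettings}.
#' @export
fasterSettings <- function(z_cut = 3,
                           metrics = c("variance", "median_gradient",
                                       "amplitude_range",
                                       "mean_amplitude_deviation")) {
  stopifnot(z_cut > 0)
  structure(list(z_cut = z_cut, metrics = metrics),
            class = "FasterSettings")
}

msToSamples <- function(ms, rate) as.integer(round(ms * rate / 1000))

#' Segment a recording around stimulus events
#'
#' One epoch per event whose name matches \code{markers}: the half-open
#' sample range
#' \code{[onset + round((start+offset) rate/1000), onset + round((end+offset) rate/1000))}.
#' Events whose epoch would exceed the recording bounds are dropped and
#' counted.  When no matching events exist, an empty EpochSet with a
#' notation is returned (not an error).
#'
#' @param rec an [EEGRecording-class].
#' @param markers character vector of event names to segment on.
#' @param settings a [segmentationSettings()].
#' @return an [EpochSet-class]; its \code{notes} record dropped or missing
#'   events.
#' @export
segmentEvents <- function(rec, markers, settings = segmentationSettings()) {
  stopifnot(length(markers) > 0)
  rate <- rec@rate
  s0 <- msToSamples(settings$window[1] + settings$timing_offset_ms, rate)
  s1 <- msToSamples(settings$window[2] + settings$timing_offset_ms, rate)
  len <- s1 - s0
  time <- (s0 + seq_len(len) - 1) * 1000 / rate - settings$timing_offset_ms
  ev <- rec@events[rec@events$name %in% markers, , drop = FALSE]
  notes <- character(0)
  missing <- setdiff(markers, ev$name)
  if (length(missing))
    notes <- c(notes, paste0("no trials detected for marker(s): ",
                             paste(missing, collapse = ", ")))
  n <- ncol(rec@data)
  starts <- ev$onset + s0
  ok <- starts >= 0 & (starts + len) <= n
  if (any(!ok))
    notes <- c(notes, paste0(sum(!ok), " event(s) dropped at recording bounds"))
  ev <- ev[ok, , drop = FALSE]
  nt <- nrow(ev)
  arr <- array(0, dim = c(nt, nrow(rec@data), len))
  for (i in seq_len(nt)) {
    a <- ev$onset[i] + s0
    arr[i, , ] <- rec@data[, (a + 1):(a + len), drop = FALSE]
  }
  cond <- ifelse(is.na(ev$condition), ev$name, ev$condition)
  new("EpochSet", data = arr, time = time, labels = rec@labels,
      rate = rate, conditions = as.character(cond),
      kept = rep(TRUE, nt), interpolated = rep(list(character(0)), nt),
      notes = notes)
}

#' Baseline-correct segmented data
#'
#' Standard mean subtraction: per trial and channel, the mean over the
#' baseline window is subtracted from the whole epoch.
#'
#' @param epochs an [EpochSet-class].
#' @param baseline_window \code{c(b0_ms, b1_ms)} within the epoch time axis.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, baseline_window = c(min(epochs@time), 0)) {
  sel <- epochs@time >= baseline_window[1] & epochs@time <= baseline_window[2]
  if (!any(sel)) stop("window error: empty baseline sample set")
  bl <- apply(epochs@data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs@data <- epochs@data - array(bl, dim = dim(epochs@data))
  epochs
}

# per-(trial, channel) statistics: variance, median absolute successive
# difference, max - min, |trial-channel mean - channel grand mean|
epochChannelMetrics <- function(epochs) {
  d <- dim(epochs@data)
  v  <- apply(epochs@data, c(1, 2), stats::var)
  mg <- apply(epochs@data, c(1, 2), function(x) stats::median(abs(diff(x))))
  rg <- apply(epochs@data, c(1, 2), function(x) max(x) - min(x))
  mn <- apply(epochs@data, c(1, 2), mean)
  dev <- abs(sweep(mn, 2, colMeans(mn), "-"))
  list(variance = v, median_gradient = mg, amplitude_range = rg,
       mean_amplitude_deviation = dev)
}

#' Flag outlying (trial, channel) pairs by segment statistics
#'
#' For each channel, each of the four metrics (variance, median gradient,
#' amplitude range, deviation from mean amplitude) is z-scored across
#' trials; a (trial, channel) pair is flagged iff any |z| exceeds
#' \code{z_cut}.
#'
#' @param epochs an [EpochSet-class] with at least 3 trials.
#' @param settings a [fasterSettings()].
#' @return logical matrix, trials x channels.
#' @export
fasterEpochChannelFlags <- function(epochs, settings = fasterSettings()) {
  if (nTrials(epochs) < 3) stop("need at least 3 trials")
  mets <- epochChannelMetrics(epochs)[settings$metrics]
  flags <- matrix(FALSE, nTrials(epochs), nChannels(epochs))
  for (m in mets) {
    z <- apply(m, 2, zScore)
    flags <- flags | abs(z) > settings$z_cut
  }
  dimnames(flags) <- list(NULL, epochs@labels)
  flags
}

#' Interpolate flagged channels within individual segments
#'
#' Flagged (trial, channel) data are replaced by the spherical-spline
#' estimate from that trial's unflagged channels; trials with fewer than 4
#' usable channels are marked for rejection instead.  Interpolated channels
#' are recorded per segment for the data-quality report.
#'
#' @param epochs an [EpochSet-class].
#' @param flags logical trials x channels matrix from
#'   [fasterEpochChannelFlags()].
#' @param montage data.frame with columns \code{label,x,y,z} covering all
#'   channels.
#' @param settings a [splineSettings()].
#' @return the repaired [EpochSet-class].
#' @export
interpolateWithinSegments <- function(epochs, flags, montage,
                                      settings = splineSettings()) {
  pos <- as.matrix(montage[match(epochs@labels, montage$label),
                           c("x", "y", "z")])
  for (tr in seq_len(nTrials(epochs))) {
    badIdx <- which(flags[tr, ])
    if (!length(badIdx)) next
    goodIdx <- setdiff(seq_len(nChannels(epochs)), badIdx)
    if (length(goodIdx) < 4) {
      epochs@kept[tr] <- FALSE
      next
    }
    est <- sphericalSplineInterpolate(
      epochs@data[tr, goodIdx, , drop = TRUE],
      pos[goodIdx, , drop = FALSE],
      pos[badIdx, , drop = FALSE], settings)
    epochs@data[tr, badIdx, ] <- est
    epochs@interpolated[[tr]] <- epochs@labels[badIdx]
  }
  epochs
}

# pooled per-channel log-density of sample values (256-bin histogram,
# add-one smoothing)
jointProbScores <- function(dat) {        # trials x channels x samples
  d <- dim(dat)
  scores <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[2])) {
    pooled <- as.vector(dat[, ch, ])
    rng <- range(pooled)
    if (diff(rng) < 1e-12) { scores[, ch] <- 0; next }
    brk <- seq(rng[1], rng[2], length.out = 257)
    counts <- tabulate(findInterval(pooled, brk, all.inside = TRUE), 256)
    dens <- log((counts + 1) / sum(counts + 1))
    for (tr in seq_len(d[1])) {
      b <- findInterval(dat[tr, ch, ], brk, all.inside = TRUE)
      scores[tr, ch] <- sum(dens[b])
    }
  }
  scores
}

#' Reject segments by amplitude and/or joint probability
#'
#' Amplitude: a trial is marked when any sample of any evaluated channel
#' lies outside \code{[amp_low, amp_high]}.  Joint probability: per channel,
#' a trial's summed sample log-density (single-electrode score) is z-scored
#' across trials, and per trial the channel scores are z-scored across
#' channels (electrode-group score); a trial is marked when either |z|
#' exceeds \code{jp_sd}.  Evaluation is restricted to \code{roi} when given.
#' All marks are applied simultaneously in one step: \code{kept} flags are
#' updated, no data are deleted.
#'
#' @param epochs an [EpochSet-class].
#' @param policy a [rejectionPolicy()].
#' @return list with \code{epochs} (flags updated) and \code{report}
#'   (counts and per-criterion marks).
#' @export
rejectSegments <- function(epochs, policy = rejectionPolicy()) {
  labels <- epochs@labels
  chans <- if (!is.null(policy$roi)) intersect(labels, policy$roi) else labels
  if (!length(chans)) stop("policy error: ROI has no channels in data")
  chIdx <- match(chans, labels)
  dat <- epochs@data[, chIdx, , drop = FALSE]
  nt <- nTrials(epochs)
  markAmp <- rep(FALSE, nt)
  markJp <- rep(FALSE, nt)
  if (policy$criteria %in% c("amplitude", "both")) {
    markAmp <- apply(dat, 1, function(tr)
      any(tr < policy$amp_low | tr > policy$amp_high))
  }
  if (policy$criteria %in% c("jointprob", "both") && nt >= 3) {
    sc <- jointProbScores(dat)
    zSingle <- apply(sc, 2, zScore)                    # across trials
    zGroup <- t(apply(sc, 1, zScore))                  # across channels
    markJp <- apply(abs(zSingle) > policy$jp_sd, 1, any) |
              apply(abs(zGroup) > policy$jp_sd, 1, any)
  }
  marks <- markAmp | markJp
  epochs@kept <- epochs@kept & !marks
  list(epochs = epochs,
       report = list(n_marked = sum(marks), amplitude = markAmp,
                     jointprob = markJp, n_kept = sum(epochs@kept)))
}

#' Split an epoch set by event marker and condition
#'
#' Returns the all-marker set, one set per marker and one set per condition
#' group; trial counts are conserved across the marker partition.  A
#' requested marker absent from the data yields an empty set with a
#' notation.
#'
#' @param epochs an [EpochSet-class] whose \code{conditions} hold marker
#'   names.
#' @param condition_map optional named list mapping condition names to
#'   marker vectors (e.g. \code{list(face = c("happy_face", "sad_face"))}).
#' @return named list of [EpochSet-class] objects: \code{all}, one per
#'   marker, one per condition.
#' @export
splitByCondition <- function(epochs, condition_map = list()) {
  takeTrials <- function(idx, note = character(0)) {
    new("EpochSet",
        data = epochs@data[idx, , , drop = FALSE], time = epochs@time,
        labels = epochs@labels, rate = epochs@rate,
        conditions = epochs@conditions[idx], kept = epochs@kept[idx],
        interpolated = epochs@interpolated[idx],
        notes = c(epochs@notes, note))
  }
  out <- list(all = epochs)
  for (m in unique(epochs@conditions))
    out[[m]] <- takeTrials(which(epochs@conditions == m))
  for (cn in names(condition_map)) {
    idx <- which(epochs@conditions %in% condition_map[[cn]])
    note <- if (!length(idx))
      paste0("no trials detected for condition: ", cn) else character(0)
    out[[cn]] <- takeTrials(idx, note)
  }
  out
}
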