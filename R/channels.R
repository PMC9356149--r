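#' Select channels by inclusion or exclusion
#'
#' Restricts a recording to channels of interest (\code{include}) or drops
#' channels of disinterest (\code{exclude}).  Removed channels are gone for
#' good: they are absent from all downstream stages and outputs.  Channel
#' order is preserved.
#'
#' @param rec an [EEGRecording-class].
#' @param mode \code{"all"}, \code{"include"} or \code{"exclude"}.
#' @param names channel names for include/exclude.
#' @return an [EEGRecording-class] with the selected channels.
#' @export
selectChannels <- function(rec, mode = c("all", "include", "exclude"),
                           names = character(0)) {
  mode <- match.arg(mode)
  if (mode == "all") return(addProvenance(rec, "select_channels",
                                          list(mode = "all")))
  unknown <- setdiff(names, rec@labels)
  if (length(unknown))
    stop("selection error: unknown channel(s): ",
         paste(unknown, collapse = ", "))
  keep <- if (mode == "include") rec@labels %in% names
          else !(rec@labels %in% names)
  rec@data <- rec@data[keep, , drop = FALSE]
  rec@labels <- rec@labels[keep]
  if (nrow(rec@montage)) {
    rec@montage <- rec@montage[rec@montage$label %in% rec@labels, , drop = FALSE]
    rownames(rec@montage) <- NULL
  }
  rec <- addProvenance(rec, "select_channels",
                       list(mode = mode, names = names))
  validObject(rec)
  rec
}

#' Downsample a recording to a target rate
#'
#' Rational-ratio resampling with a windowed-sinc anti-aliasing filter
#' (polyphase-equivalent: zero-stuff upsample, lowpass at the narrower
#' Nyquist, decimate).  Event onsets are rescaled by the same ratio.
#' Upsampling is refused.
#'
#' @param rec an [EEGRecording-class].
#' @param target target rate in Hz (the pipeline offers 250, 500 or 1000).
#' @return the resampled [EEGRecording-class].
#' @export
resampleRecording <- function(rec, target) {
  if (target > rec@rate)
    stop("upsample error: users may not upsample data (",
         rec@rate, " -> ", target, " Hz)")
  if (target == rec@rate) return(addProvenance(rec, "resample",
                                               list(target = target)))
  frac <- ratApprox(target / rec@rate)
  p <- frac[1]; q <- frac[2]
  nOut <- round(ncol(rec@data) * target / rec@rate)
  newData <- t(apply(rec@data, 1, resampleVector, p = p, q = q, nOut = nOut))
  rec@events$onset <- as.integer(pmin(round(rec@events$onset * target / rec@rate),
                                      nOut - 1L))
  rec@rate <- target
  setRecData(rec, newData, "resample", list(target = target))
}

# continued-fraction rational approximation of a ratio in (0, 1]
ratApprox <- function(x, tol = 1e-9, maxden = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > maxden) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * x) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

resampleVector <- function(x, p, q, nOut) {
  n <- length(x)
  # reflect-pad in input domain to suppress edge transients
  pad <- min(n - 1L, ceiling(12 * q / p) + 12L)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  up <- numeric(length(xp) * p)
  up[seq(1, length(up), by = p)] <- xp * p
  m <- max(p, q)
  taps <- 2L * 12L * m + 1L                  # 12 input-sample half-length
  cutoff <- 0.98 / m                         # of upsampled Nyquist
  kern <- signal::fir1(taps - 1L, cutoff, type = "low")
  y <- zeroPhaseFir(up, kern)
  y <- y[seq(1, length(y), by = q)]
  offset <- floor(pad * p / q)
  y <- y[(offset + 1):(offset + nOut)]
  y
}
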