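#' Filtering specification
#'
#' @param kind \code{"fir_hamming"} (zero-phase Hamming windowed-sinc FIR) or
#'   \code{"iir_butterworth"} (forward-backward Butterworth cascade).
#' @param highpass high-pass edge in Hz, or \code{NULL}.
#' @param lowpass low-pass edge in Hz, or \code{NULL}.
#' @param pre_clean_lowpass cutoff of the fixed lowpass applied before
#'   artifact rejection and bad-channel detection (default 100 Hz).
#' @param order \code{"auto"} or an integer FIR tap count / IIR order.
#' @return a validated list of class \code{FilterSpec}.
#' @export
filterSpec <- function(kind = c("fir_hamming", "iir_butterworth"),
                       highpass = NULL, lowpass = NULL,
                       pre_clean_lowpass = 100, order = "auto") {
  kind <- match.arg(kind)
  if (!is.null(highpass) && !is.null(lowpass) && highpass >= lowpass)
    stop("spec error: highpass must be below lowpass")
  if (!is.null(highpass) && highpass < 0) stop("spec error: negative highpass")
  structure(list(kind = kind, highpass = highpass, lowpass = lowpass,
                 pre_clean_lowpass = pre_clean_lowpass, order = order),
            class = "FilterSpec")
}

# reflection padding that tiles reflections when pad exceeds signal length
padReflect <- function(x, pad) {
  n <- length(x)
  if (n < 2) return(c(rep(x, pad), x, rep(x, pad)))
  period <- c(x, rev(x[c(-1, -n)]))            # length 2n - 2, smooth tiling
  idx <- function(k) period[((k - 1) %% length(period)) + 1]
  left <- idx(seq(1 - pad, 0))
  right <- idx(seq(n + 1, n + pad))
  c(left, x, right)
}

# zero-phase FIR: symmetric kernel, delay-compensated single pass.
# Caller-visible length equals input length.
zeroPhaseFir <- function(x, kern, pad = NULL) {
  taps <- length(kern)
  half <- (taps - 1) %/% 2
  n <- length(x)
  if (is.null(pad)) pad <- half
  xp <- if (pad > 0) padReflect(x, pad) else x
  yf <- stats::convolve(xp, rev(kern), type = "open")
  start <- half + pad + 1
  yf[start:(start + n - 1)]
}

# FIR tap count from the transition-width heuristic:
# tb = min(max(0.25 * f_edge, 2 Hz), f_edge) per edge, taps = ceil(3.3*rate/tb),
# rounded up to odd.
firTaps <- function(rate, edges) {
  tb <- vapply(edges, function(f) min(max(0.25 * f, 2), f), 0)
  taps <- ceiling(3.3 * rate / min(tb))
  if (taps %% 2 == 0) taps <- taps + 1
  as.integer(taps)
}

designFir <- function(rate, highpass, lowpass, order = "auto") {
  nyq <- rate / 2
  if (!is.null(lowpass) && lowpass >= nyq)
    stop("spec error: lowpass at or above Nyquist")
  if (is.null(highpass) && is.null(lowpass)) return(NULL)
  edges <- c(highpass, lowpass)
  taps <- if (identical(order, "auto")) firTaps(rate, edges) else as.integer(order)
  if (taps %% 2 == 0) taps <- taps + 1L
  if (!is.null(highpass) && !is.null(lowpass))
    signal::fir1(taps - 1L, c(highpass, lowpass) / nyq, type = "pass")
  else if (!is.null(lowpass))
    signal::fir1(taps - 1L, lowpass / nyq, type = "low")
  else
    signal::fir1(taps - 1L, highpass / nyq, type = "high")
}

#' Zero-phase FIR band filtering
#'
#' Hamming windowed-sinc FIR filter applied without group delay (symmetric
#' kernel, reflection padding).  The tap count is auto-estimated from the
#' transition width \code{tb = min(max(0.25 f, 2 Hz), f)} of the narrower
#' edge as \code{ceil(3.3 rate / tb)}, rounded up to odd.
#'
#' @param rec an [EEGRecording-class].
#' @param spec a [filterSpec()] (its \code{highpass}/\code{lowpass} are used).
#' @return the filtered [EEGRecording-class].
#' @export
firBandpass <- function(rec, spec) {
  kern <- designFir(rec@rate, spec$highpass, spec$lowpass, spec$order)
  if (is.null(kern)) return(addProvenance(rec, "fir_filter", list(identity = TRUE)))
  out <- t(apply(rec@data, 1, zeroPhaseFir, kern = kern))
  setRecData(rec, out, "fir_filter",
             list(highpass = spec$highpass, lowpass = spec$lowpass,
                  taps = length(kern)))
}

# ---- Butterworth second-order-section design ------------------------------

# Analytic digital Butterworth design (bilinear transform), returned as a
# list of biquads; each section is gain-normalized at DC (lowpass) or
# Nyquist (highpass).  Transfer-function forms of high-order Butterworth
# filters at ERP cutoffs are numerically singular, hence the cascade.
butterSos <- function(n, fc, rate, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= rate / 2) stop("spec error: cutoff outside (0, Nyquist)")
  fs2 <- 2 * rate
  wc <- fs2 * tan(pi * fc / rate)
  k <- seq_len(n)
  s <- exp(1i * pi * (2 * k + n - 1) / (2 * n))        # prototype poles, Re<0
  sp <- if (type == "low") wc * s else wc / s
  zp <- (fs2 + sp) / (fs2 - sp)                        # bilinear poles
  zz <- if (type == "low") rep(-1 + 0i, n) else rep(1 + 0i, n)
  if (any(abs(zp) >= 1)) stop("filter error: unstable design")
  # pair into conjugate biquads (odd n leaves one real pole)
  ord <- order(abs(Im(zp)), decreasing = TRUE)
  zp <- zp[ord]
  sections <- list()
  used <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (!used[i]) {
      if (abs(Im(zp[i])) > 1e-12) {
        j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8)[1]
        used[c(i, j)] <- TRUE
        a <- c(1, -Re(zp[i] + zp[j]), Re(zp[i] * zp[j]))
        b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
      } else {
        used[i] <- TRUE
        a <- c(1, -Re(zp[i]))
        b <- if (type == "low") c(1, 1) else c(1, -1)
      }
      ref <- if (type == "low") 1 else -1                 # z at DC / Nyquist
      g <- abs(sum(a * ref^(seq_along(a) - 1)) /
               sum(b * ref^(seq_along(b) - 1)))
      sections[[length(sections) + 1]] <- list(b = b * g, a = a)
    }
    i <- i + 1
  }
  sections
}

filtfiltSos <- function(x, sections) {
  n <- length(x)
  pad <- min(n - 1L, 30000L)
  xp <- c(2 * x[1] - rev(x[seq(2, pad + 1)]), x,
          2 * x[n] - rev(x[seq(n - pad, n - 1)]))
  for (s in sections) {
    xp <- as.numeric(signal::filter(s$b, s$a, xp))
    xp <- rev(as.numeric(signal::filter(s$b, s$a, rev(xp))))
  }
  xp[(pad + 1):(pad + n)]
}

# literal published order rule, capped for stability
iirOrder <- function(rate, highpass) {
  if (is.null(highpass) || highpass <= 0) return(8L)
  as.integer(min(3 * floor(rate / highpass), 8))
}

#' Zero-phase Butterworth (IIR) band filtering
#'
#' Butterworth filtering applied forward-backward (zero phase) through a
#' cascade of analytically designed second-order sections.  High-pass and
#' low-pass edges are applied as separate cascades.  The design order is the
#' literal rule \code{3 * floor(rate / highpass)} capped at 8 (the uncapped
#' rule yields orders in the thousands for ERP cutoffs and cannot be realized
#' stably).
#'
#' @inheritParams firBandpass
#' @return the filtered [EEGRecording-class].
#' @export
iirBandpass <- function(rec, spec) {
  if (is.null(spec$highpass) && is.null(spec$lowpass))
    return(addProvenance(rec, "iir_filter", list(identity = TRUE)))
  ord <- if (identical(spec$order, "auto")) iirOrder(rec@rate, spec$highpass)
         else as.integer(spec$order)
  sections <- list()
  if (!is.null(spec$highpass))
    sections <- c(sections, butterSos(ord, spec$highpass, rec@rate, "high"))
  if (!is.null(spec$lowpass))
    sections <- c(sections, butterSos(ord, spec$lowpass, rec@rate, "low"))
  out <- t(apply(rec@data, 1, filtfiltSos, sections = sections))
  setRecData(rec, out, "iir_filter",
             list(highpass = spec$highpass, lowpass = spec$lowpass,
                  order = ord))
}

#' Fixed 100 Hz lowpass applied before artifact handling
#'
#' Applied ahead of bad-channel detection and wavelet thresholding so those
#' stages evaluate the frequency range of neural activity.  A no-op when the
#' cutoff is at or above Nyquist.
#'
#' @param rec an [EEGRecording-class].
#' @param cutoff lowpass edge in Hz (default 100).
#' @return the filtered [EEGRecording-class].
#' @export
preCleanLowpass <- function(rec, cutoff = 100) {
  if (cutoff >= rec@rate / 2)
    return(addProvenance(rec, "pre_clean_lowpass", list(skipped = TRUE)))
  firBandpass(rec, filterSpec("fir_hamming", lowpass = cutoff))
}
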