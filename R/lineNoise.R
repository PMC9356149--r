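#' Settings for multi-taper line-noise removal
#'
#' @param target_freq mains frequency in Hz (60 or 50).
#' @param extra_freqs additional (harmonic) frequencies to remove.
#' @param scan_halfwidth half-width in Hz of the scan around each target
#'   (default 2): the sinusoid is fitted at the scan frequency maximizing the
#'   detection statistic.
#' @param window_s sliding-window length in seconds (default 4).
#' @param step_s window step in seconds (default 1).
#' @param smoothing_tau exponential smoothing constant, in window steps, for
#'   the complex sinusoid estimates across windows (default 100).
#' @param alpha significance level of the Thomson F-test below which a
#'   window's fitted sinusoid is subtracted (default 0.01).
#' @param taper_bandwidth Slepian taper half-bandwidth in Hz (default 2);
#'   sets the taper count K = floor(2 * taper_bandwidth * window_s) - 1.
#' @param legacy if TRUE, disable the across-window smoothing (same
#'   algorithm otherwise).
#' @return a validated list of class \code{LineNoiseSettings}.
#' @export
lineNoiseSettings <- function(target_freq = 60, extra_freqs = numeric(0),
                              scan_halfwidth = 2, window_s = 4, step_s = 1,
                              smoothing_tau = 100, alpha = 0.01,
                              taper_bandwidth = 2, legacy = FALSE) {
  if (target_freq <= 0) stop("target_freq must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  K <- floor(2 * taper_bandwidth * window_s) - 1
  if (K < 1) stop("window too short for the taper bandwidth")
  structure(list(target_freq = target_freq, extra_freqs = extra_freqs,
                 scan_halfwidth = scan_halfwidth, window_s = window_s,
                 step_s = step_s, smoothing_tau = smoothing_tau,
                 alpha = alpha, taper_bandwidth = taper_bandwidth,
                 legacy = legacy),
            class = "LineNoiseSettings")
}

# ---- discrete prolate spheroidal sequences --------------------------------

.dpssCache <- new.env(parent = emptyenv())

# Slepian tapers from the symmetric tridiagonal formulation, solved by
# Sturm-sequence bisection for the K largest eigenvalues plus inverse
# iteration (O(K N) per taper).  Columns are unit-norm, ordered by
# decreasing concentration.
dpssTapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpssCache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  e <- t0[-1] * (n - t0[-1]) / 2

  countBelow <- function(x) {                   # eigenvalues < x
    cnt <- 0L; q <- d[1] - x
    if (q < 0) cnt <- 1L
    for (i in 2:n) {
      q <- d[i] - x - e[i - 1]^2 / if (q == 0) 1e-300 else q
      if (q < 0) cnt <- cnt + 1L
    }
    cnt
  }
  lo0 <- min(d - c(abs(e), 0) - c(0, abs(e)))
  hi0 <- max(d + c(abs(e), 0) + c(0, abs(e)))
  eigK <- numeric(k)
  for (j in seq_len(k)) {                       # j-th largest eigenvalue
    target <- n - j                             # want count < x == n - j + 1 above
    lo <- lo0; hi <- hi0
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (countBelow(mid) >= target + 1L) hi <- mid else lo <- mid
      if (hi - lo < 1e-9 * max(1, abs(hi))) break
    }
    eigK[j] <- (lo + hi) / 2
  }
  solveShift <- function(lam, b) {              # (T - lam I) x = b, Thomas
    dd <- d - lam
    cp <- numeric(n - 1); dp <- numeric(n)
    denom <- if (abs(dd[1]) < 1e-12) 1e-12 else dd[1]
    cp[1] <- e[1] / denom; dp[1] <- b[1] / denom
    for (i in 2:n) {
      m <- dd[i] - e[i - 1] * cp[i - 1]
      if (abs(m) < 1e-12) m <- 1e-12
      if (i < n) cp[i] <- e[i] / m
      dp[i] <- (b[i] - e[i - 1] * dp[i - 1]) / m
    }
    x <- numeric(n); x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  H <- matrix(0, n, k)
  for (j in seq_len(k)) {
    # deterministic non-degenerate start vector (keeps user RNG untouched)
    v <- sin(seq_len(n) * (0.7 + 0.37 * j)) + 0.01 * cos(seq_len(n) * 0.11)
    for (it in 1:4) {
      v <- solveShift(eigK[j] + 1e-8, v)
      if (j > 1) v <- v - H[, 1:(j - 1), drop = FALSE] %*%
        crossprod(H[, 1:(j - 1), drop = FALSE], v)
      v <- v / sqrt(sum(v^2))
    }
    # sign convention: symmetric tapers positive mean, antisymmetric
    # positive initial lobe
    if (sum(v) < 0 || (abs(sum(v)) < 1e-8 && v[2] < 0)) v <- -v
    H[, j] <- v
  }
  .dpssCache[[key]] <- H
  H
}

# ---- sinusoid fit ---------------------------------------------------------

#' Multi-taper sinusoid fit at (or near) a target frequency
#'
#' Estimates the amplitude and phase of a deterministic sinusoid by
#' regression on Slepian-tapered data, with Thomson's harmonic F-test
#' (F with 2 and 2K-2 df) for significance.  The fit is taken at the scan
#' frequency within \code{freq +/- scan_halfwidth} maximizing the F
#' statistic, on the periodogram-resolution grid.
#'
#' @param window numeric vector, one channel's samples; its length must be
#'   \code{window_s * rate}.
#' @param rate sampling rate, Hz.
#' @param freq target frequency, Hz.
#' @param settings a [lineNoiseSettings()].
#' @return list with \code{amplitude} (uV), \code{phase} (rad), \code{freq}
#'   (the selected scan frequency), \code{p} (F-test p-value) and
#'   \code{coef} (the complex amplitude, window-start phase reference).
#' @export
fitSinusoidMultitaper <- function(window, rate, freq, settings) {
  if (freq >= rate / 2) stop("frequency error: at or above Nyquist")
  n <- length(window)
  K <- floor(2 * settings$taper_bandwidth * settings$window_s) - 1
  nw <- settings$taper_bandwidth * settings$window_s
  H <- dpssTapers(n, nw, K)
  H0 <- colSums(H)
  TF <- stats::mvfft(H * window)                  # N x K eigencoefficients
  fgrid <- (0:(n - 1)) * rate / n
  bins <- which(fgrid >= freq - settings$scan_halfwidth &
                fgrid <= freq + settings$scan_halfwidth & fgrid < rate / 2)
  J <- TF[bins, , drop = FALSE]
  sumH0sq <- sum(H0^2)
  mu <- as.vector(J %*% H0) / sumH0sq
  resid <- J - outer(mu, H0)
  denom <- rowSums(Mod(resid)^2)
  Fstat <- (K - 1) * Mod(mu)^2 * sumH0sq / pmax(denom, 1e-300)
  i <- which.max(Fstat)
  p <- stats::pf(Fstat[i], 2, 2 * K - 2, lower.tail = FALSE)
  list(amplitude = 2 * Mod(mu[i]), phase = Arg(mu[i]),
       freq = fgrid[bins[i]], p = p, coef = mu[i])
}

# ---- removal --------------------------------------------------------------

#' Remove mains-line noise by multi-taper sinusoid regression
#'
#' Sliding windows (\code{window_s} long, \code{step_s} apart) are fitted per
#' channel at the target frequency and each extra frequency; the fitted
#' sinusoid is subtracted only in windows where the F-test is significant
#' (\code{p < alpha}).  Complex window estimates are smoothed across time
#' with exponential weight \code{exp(-distance/tau)} before subtraction, and
#' overlapping windows are blended by overlap-add with a linear cross-fade.
#' A pre-removal copy is returned for quality control.
#'
#' @param rec an [EEGRecording-class].
#' @param settings a [lineNoiseSettings()].
#' @return list with elements \code{rec} (cleaned) and \code{pre} (the
#'   unmodified input, retained for QC).
#' @export
removeLineNoise <- function(rec, settings = lineNoiseSettings()) {
  pre <- rec
  n <- ncol(rec@data)
  win <- round(settings$window_s * rec@rate)
  step <- round(settings$step_s * rec@rate)
  if (win > n) { win <- n }
  starts <- seq(0, n - win, by = step)
  if (max(starts) < n - win) starts <- c(starts, n - win)
  freqs <- c(settings$target_freq, settings$extra_freqs)
  freqs <- freqs[freqs < rec@rate / 2]
  fade <- pmin(seq_len(win), rev(seq_len(win)))   # linear cross-fade
  fade <- fade / max(fade)
  out <- rec@data
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    removal <- numeric(n)
    wsum <- numeric(n)
    for (f in freqs) {
      nW <- length(starts)
      coefAbs <- complex(nW); pvals <- numeric(nW); fsel <- numeric(nW)
      for (w in seq_len(nW)) {
        seg <- x[(starts[w] + 1):(starts[w] + win)]
        fit <- fitSinusoidMultitaper(seg, rec@rate, f, settings)
        fsel[w] <- fit$freq
        pvals[w] <- fit$p
        # re-reference phase to absolute time
        coefAbs[w] <- fit$coef * exp(-1i * 2 * pi * fit$freq * starts[w] / rec@rate)
      }
      sig <- pvals < settings$alpha
      if (!any(sig)) next
      coefSm <- coefAbs
      if (!settings$legacy && nW > 1) {
        idx <- seq_len(nW)
        for (w in idx) {
          kern <- exp(-abs(idx - w) / settings$smoothing_tau)
          coefSm[w] <- sum(kern * coefAbs) / sum(kern)
        }
      }
      for (w in which(sig)) {
        tAbs <- starts[w]:(starts[w] + win - 1)
        s <- Re(2 * coefSm[w] * exp(1i * 2 * pi * fsel[w] * tAbs / rec@rate))
        removal[tAbs + 1] <- removal[tAbs + 1] + fade * s
        wsum[tAbs + 1] <- wsum[tAbs + 1] + fade
      }
    }
    cover <- wsum > 0
    removal[cover] <- removal[cover] / wsum[cover]
    out[ch, ] <- x - removal
  }
  rec <- setRecData(rec, out, "line_noise",
                    list(target = settings$target_freq,
                         extra = settings$extra_freqs))
  list(rec = rec, pre = pre)
}
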