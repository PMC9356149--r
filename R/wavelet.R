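# Undecimated (maximal-overlap / stationary) wavelet transform with the
# coiflet-4 filter pair, and universal-threshold artifact splitting.

# coiflet-4 orthonormal analysis filters (published constants)
.coif4_lo <- c(
  -1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05,
  6.233885431278719e-05, -2.599743371222568e-04, -5.890202246332165e-04,
  1.2665610789256603e-03, 3.7514346971460866e-03, -5.6582838001308835e-03,
  -1.5211728187697211e-02, 2.508225333794961e-02, 3.933442260558915e-02,
  -9.622042453595264e-02, -6.662747236681717e-02, 4.3438603311435653e-01,
  7.822389344242826e-01, 4.1530842700068227e-01, -5.607731960356926e-02,
  -8.126671024919373e-02, 2.668230466960483e-02, 1.606894713157503e-02,
  -7.346167936268051e-03, -1.629492425226786e-03, 8.92313902537003e-04)
.coif4_hi <- rev(.coif4_lo) * rep(c(1, -1), 12)

circShift <- function(v, s) {
  n <- length(v)
  v[((seq_len(n) - 1 - s) %% n) + 1]
}

# Maximal-overlap DWT, circular, to `levels` levels.  Returns a list with
# detail matrices W (n x levels) and the final approximation V.
modwt <- function(x, levels) {
  n <- length(x)
  g <- .coif4_lo / sqrt(2)
  h <- .coif4_hi / sqrt(2)
  W <- matrix(0, n, levels)
  V <- x
  for (j in seq_len(levels)) {
    up <- 2^(j - 1)
    Wj <- numeric(n); Vj <- numeric(n)
    for (l in seq_along(g)) {
      sh <- circShift(V, (l - 1) * up)
      Wj <- Wj + h[l] * sh
      Vj <- Vj + g[l] * sh
    }
    W[, j] <- Wj
    V <- Vj
  }
  list(W = W, V = V)
}

imodwt <- function(coeffs) {
  g <- .coif4_lo / sqrt(2)
  h <- .coif4_hi / sqrt(2)
  V <- coeffs$V
  levels <- ncol(coeffs$W)
  n <- length(V)
  for (j in rev(seq_len(levels))) {
    up <- 2^(j - 1)
    Vn <- numeric(n)
    Wj <- coeffs$W[, j]
    for (l in seq_along(g)) {
      Vn <- Vn + h[l] * circShift(Wj, -(l - 1) * up) +
                 g[l] * circShift(V, -(l - 1) * up)
    }
    V <- Vn
  }
  V
}

#' Wavelet-thresholding settings
#'
#' @param family wavelet family; \code{"coiflet-4"} (the only built-in).
#' @param mode \code{"soft"} (amplitude-preserving shrinkage, suited to
#'   low-artifact data) or \code{"hard"} (more aggressive removal, suited to
#'   high- or variable-artifact data).
#' @param levels decomposition depth, or \code{"auto"} =
#'   \code{round(log2(rate)) - 1} so the coarsest detail band reaches about
#'   1 Hz.
#' @param protect_approximation keep the approximation (lowest-frequency)
#'   band untouched (default TRUE).
#' @return list of class \code{WaveletSettings}.
#' @export
waveletSettings <- function(family = "coiflet-4", mode = c("soft", "hard"),
                            levels = "auto", protect_approximation = TRUE) {
  mode <- match.arg(mode)
  if (!identical(family, "coiflet-4"))
    stop("only the coiflet-4 family is built in")
  structure(list(family = family, mode = mode, levels = levels,
                 protect_approximation = protect_approximation,
                 threshold_rule = "universal"),
            class = "WaveletSettings")
}

#' Split a wavelet coefficient into artifact and retained parts
#'
#' Soft: \code{artifact = sign(w) max(|w| - lambda, 0)} (so the retained part
#' is clipped at \code{lambda}); hard: the whole coefficient is artifact iff
#' \code{|w| > lambda}.  In both modes \code{artifact + retained == w}
#' exactly.
#'
#' @param w coefficient value(s).
#' @param lambda non-negative threshold.
#' @param mode \code{"soft"} or \code{"hard"}.
#' @return list with \code{artifact} and \code{retained}.
#' @export
thresholdCoefficients <- function(w, lambda, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(lambda >= 0)
  if (mode == "soft") {
    artifact <- sign(w) * pmax(abs(w) - lambda, 0)
  } else {
    artifact <- w * (abs(w) > lambda)
  }
  list(artifact = artifact, retained = w - artifact)
}

nextPow2 <- function(n) 2^ceiling(log2(n))

#' Artifact correction by stationary wavelet thresholding
#'
#' Per channel, the continuous signal is reflection-padded to a power-of-two
#' length, decomposed with the undecimated coiflet-4 transform to L levels
#' (auto: \code{round(log2(rate)) - 1}, reaching about 1 Hz), and each detail
#' level is split at the universal threshold
#' \code{lambda_j = s_j sqrt(2 ln N)} with the level noise scale
#' \code{s_j = median(|d_j|) / 0.6745}.  Supra-threshold coefficient content
#' is treated as artifact and removed; the cleaned signal is the
#' reconstruction of the retained parts (approximation band untouched by
#' default).  The removed signal is returned for quality control and
#' satisfies \code{cleaned + removed == input} exactly.
#'
#' @param rec a continuous (pre-segmentation) [EEGRecording-class].
#' @param settings a [waveletSettings()].
#' @return list with \code{rec} (cleaned recording) and \code{removed}
#'   (recording holding the removed artifact signal).
#' @export
waveletClean <- function(rec, settings = waveletSettings()) {
  n <- ncol(rec@data)
  levels <- if (identical(settings$levels, "auto"))
    max(1L, round(log2(rec@rate)) - 1L) else as.integer(settings$levels)
  if (n < 2^levels)
    stop("length error: data shorter than 2^levels samples")
  # full reflection makes the circular extension continuous at the wrap
  npad <- 2L * n
  cleaned <- rec@data
  for (ch in seq_len(nrow(cleaned))) {
    x <- cleaned[ch, ]
    xp <- c(x, rev(x))
    dec <- modwt(xp, levels)
    lam <- sqrt(2 * log(npad))
    for (j in seq_len(levels)) {
      s <- stats::median(abs(dec$W[, j])) / 0.6745
      parts <- thresholdCoefficients(dec$W[, j], s * lam, settings$mode)
      dec$W[, j] <- parts$retained
    }
    if (!settings$protect_approximation) {
      s <- stats::median(abs(dec$V)) / 0.6745
      parts <- thresholdCoefficients(dec$V, s * lam, settings$mode)
      dec$V <- parts$retained
    }
    cleaned[ch, ] <- imodwt(dec)[seq_len(n)]
  }
  removedData <- rec@data - cleaned
  removed <- rec
  removed@data <- removedData
  rownames(removed@data) <- removed@labels
  rec <- setRecData(rec, cleaned, "wavelet_threshold",
                    list(mode = settings$mode, levels = levels))
  list(rec = rec, removed = removed)
}
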